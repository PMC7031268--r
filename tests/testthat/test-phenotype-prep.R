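heiferRec <- function(ageIns = 400, NINS = 2, IFL = 30, censored = FALSE,
                      id = "h1") {
  data.frame(id = id, stage = "heifer", parity = 1, herd = 1, ym = 1,
             ageIns = ageIns, ageCalv = NA_real_, IFL = IFL, NINS = NINS,
             ICF = NA_real_, censored = censored, stringsAsFactors = FALSE)
}
cowRec <- function(ageCalv = 800, NINS = 2, IFL = 40, ICF = 60,
                   censored = FALSE, id = "c1") {
  data.frame(id = id, stage = "cow", parity = 1, herd = 1, ym = 1,
             ageIns = NA_real_, ageCalv = ageCalv, IFL = IFL, NINS = NINS,
             ICF = ICF, censored = censored, stringsAsFactors = FALSE)
}

test_that("editing bounds are strict and attributed to the first rule", {
  ed <- editRecords(rbind(heiferRec(ageIns = 270), heiferRec(ageIns = 271),
                          heiferRec(ageIns = 899), heiferRec(ageIns = 900)))
  expect_equal(nrow(ed$records), 2)
  expect_equal(ed$report$removed[ed$report$Var1 == "ageIns"], 2)

  ed2 <- editRecords(rbind(cowRec(ICF = 230), cowRec(ICF = 229),
                           cowRec(NINS = 8), cowRec(IFL = 365)))
  expect_equal(nrow(ed2$records), 1)
  expect_equal(ed2$records$ICF, 229)

  # record violating several rules counts once, under the first
  ed3 <- editRecords(heiferRec(ageIns = 100, NINS = 9, IFL = 400))
  expect_equal(ed3$report$removed[ed3$report$Var1 == "ageIns"], 1)
  expect_equal(sum(ed3$report$removed), 1)
})

test_that("a toy table with three single-rule violations keeps seven", {
  tab <- rbind(heiferRec(id = "a"), heiferRec(id = "b"), heiferRec(id = "c"),
               heiferRec(id = "d"), cowRec(id = "e"), cowRec(id = "f"),
               cowRec(id = "g"),
               heiferRec(id = "x", NINS = 10),
               cowRec(id = "y", ageCalv = 1200),
               cowRec(id = "z", IFL = 400))
  ed <- editRecords(tab)
  expect_equal(nrow(ed$records), 7)
  expect_setequal(ed$records$id, letters[1:7])
})

test_that("incomplete records are rejected with reason incomplete", {
  bad <- heiferRec(); bad$IFL <- NA_real_
  ed <- editRecords(rbind(bad, heiferRec(id = "ok")))
  expect_equal(nrow(ed$records), 1)
  expect_equal(ed$report$removed[ed$report$Var1 == "incomplete"], 1)
})

test_that("editing is idempotent", {
  ped <- simulatePedigree(nFounders = 60, nGenerations = 1,
                          siresPerGeneration = 5, offspringPerDam = 3,
                          seed = 8)
  rec <- simulateFertilityRecords(ped, seed = 4)
  once <- editRecords(rec)
  twice <- editRecords(once$records)
  expect_identical(twice$records, once$records)
  expect_equal(sum(twice$report$removed), 0)
})

test_that("censoring penalties add 21 days and one insemination", {
  rec <- rbind(heiferRec(IFL = 40, NINS = 2, censored = TRUE),
               heiferRec(IFL = 40, NINS = 2, censored = FALSE, id = "h2"))
  pen <- applyCensoringPenalty(rec)
  expect_equal(pen$IFL, c(61, 40))
  expect_equal(pen$NINS, c(3, 2))
  # all-censored table shifts the mean by exactly 21
  allc <- rbind(heiferRec(IFL = 10, censored = TRUE),
                heiferRec(IFL = 50, censored = TRUE, id = "h3"))
  expect_equal(mean(applyCensoringPenalty(allc)$IFL) - mean(allc$IFL), 21)
})

test_that("reliability and weights follow their defining formulas", {
  expect_equal(reliability(0.04, 1), 0.04)
  expect_equal(reliability(0.04, 3), 0.12 / 1.08)
  expect_equal(reliability(0.02, 3), 0.06 / 1.04)  # ~0.0577
  expect_error(reliability(0.04, 0), "at least 1")
  expect_error(reliability(1.2, 1), "strictly")

  # increasing in both n and h2
  grid <- expand.grid(h2 = c(0.01, 0.05, 0.2, 0.6), n = 1:5)
  r <- reliability(grid$h2, grid$n)
  for (h in unique(grid$h2))
    expect_true(all(diff(r[grid$h2 == h][order(grid$n[grid$h2 == h])]) > 0))
  for (n in unique(grid$n))
    expect_true(all(diff(r[grid$n == n][order(grid$h2[grid$n == n])]) > 0))

  w <- residualWeights(0.5)
  expect_equal(w$w, 1)
  expect_equal(residualWeights(c(0.3, 0.3))$wstar, c(1, 1))
  w2 <- residualWeights(c(0.1, 0.2))
  expect_equal(w2$w, c(1 / 9, 1 / 4))
  expect_equal(w2$wstar, c(0.6154, 1.3846), tolerance = 1e-4)
  expect_equal(mean(w2$wstar), 1)
  expect_error(residualWeights(1), "\\[0, 1\\)")
})

test_that("the sire model recovers simulated variance components", {
  set.seed(31)
  ns <- 120; k <- 18
  sires <- sprintf("S%03d", 1:ns)
  ped <- Pedigree(id = sires, sire = rep(NA, ns), dam = rep(NA, ns))
  sEff <- rnorm(ns, 0, sqrt(0.25))
  n <- ns * k
  herd <- sample.int(6, n, replace = TRUE)
  herdEff <- c(0, 3, -2, 5, 1, -4)
  age <- round(rnorm(n, 450, 50))
  daughters <- sprintf("D%04d", 1:n)
  pedAll <- Pedigree(id = c(sires, daughters),
                     sire = c(rep(NA, ns), rep(sires, each = k)),
                     dam = rep(NA, ns + n))
  y <- 30 + herdEff[herd] + 0.05 * (age - 450) +
    rep(sEff, each = k) + rnorm(n, 0, 2)
  rec <- data.frame(id = daughters, stage = "heifer", parity = 1,
                    herd = herd, ym = sample.int(4, n, TRUE), ageIns = age,
                    ageCalv = NA_real_, IFL = y, NINS = 2, ICF = NA_real_,
                    censored = FALSE, stringsAsFactors = FALSE)
  fit <- fitSireModel(rec, ped, ped = pedAll, stage = "heifer")
  est <- vcEstimates(fit@vc)
  se <- vcSE(fit@vc)
  expect_true(isConverged(fit@vc))
  expect_lt(abs(est["sire"] - 0.25), 2 * se["sire"])
  expect_lt(abs(est["residual"] - 4), 2 * se["residual"])
  # sire-model heritability identity as an external check
  h2 <- 4 * est["sire"] / (est["sire"] + est["residual"])
  h2true <- 4 * 0.25 / 4.25
  expect_lt(abs(h2 - h2true), 0.5 * h2true)

  # pre-correction strips fixed effects: corrected values correlate with
  # the simulated sire + residual part
  pc <- precorrect(fit)
  truth <- rep(sEff, each = k) + (y - 30 - herdEff[herd] -
                                    0.05 * (age - 450) - rep(sEff, each = k))
  expect_gt(cor(pc$yc[match(daughters, pc$id)], truth), 0.99)
})

test_that("single-herd data folds the herd effect into the intercept", {
  set.seed(5)
  ns <- 20; k <- 6
  sires <- sprintf("S%02d", 1:ns)
  daughters <- sprintf("D%03d", 1:(ns * k))
  ped <- Pedigree(id = c(sires, daughters),
                  sire = c(rep(NA, ns), rep(sires, each = k)),
                  dam = rep(NA, ns + ns * k))
  rec <- data.frame(id = daughters, stage = "heifer", parity = 1, herd = 1,
                    ym = 1, ageIns = 400, ageCalv = NA_real_,
                    IFL = rnorm(ns * k, 25, 4), NINS = 2, ICF = NA_real_,
                    censored = FALSE, stringsAsFactors = FALSE)
  expect_message(fit <- fitSireModel(rec, ped, stage = "heifer"),
                 "single herd")
  expect_named(fit@fixef, "(Intercept)")
  expect_true(isConverged(fit@vc))
})

test_that("cow pre-correction averages residuals and excludes pe", {
  set.seed(41)
  ns <- 40; cowsPerSire <- 8
  sires <- sprintf("S%02d", 1:ns)
  cows <- sprintf("C%03d", 1:(ns * cowsPerSire))
  ped <- Pedigree(id = c(sires, cows),
                  sire = c(rep(NA, ns), rep(sires, each = cowsPerSire)),
                  dam = rep(NA, ns + length(cows)))
  nPar <- sample(1:3, length(cows), TRUE)
  idx <- rep(seq_along(cows), nPar)
  herd <- sample.int(5, length(idx), TRUE)
  rec <- data.frame(id = cows[idx], stage = "cow",
                    parity = unlist(lapply(nPar, seq_len)),
                    herd = herd, ym = sample.int(6, length(idx), TRUE),
                    ageIns = NA_real_,
                    ageCalv = 700 + 380 * (unlist(lapply(nPar, seq_len)) - 1) +
                      round(rnorm(length(idx), 0, 25)),
                    IFL = rnorm(length(idx), 70, 10), NINS = 2,
                    ICF = rnorm(length(idx), 50, 8), censored = FALSE,
                    stringsAsFactors = FALSE)
  fit <- fitSireModel(rec, ped, stage = "cow", trait = "IFL")
  pc <- precorrect(fit, h2 = 0.02)
  expect_equal(nrow(pc), length(cows))
  expect_equal(pc$n[match(cows, pc$id)], nPar)
  expect_equal(mean(pc$wstar), 1)
  expect_true(all(pc$r2 >= 0 & pc$r2 < 1))
  # reconstructed identity: yc = sire BLUP + mean residual per animal
  sHat <- fit@sireBlup
  recS <- fit@records$.sire
  manual <- tapply(fit@residuals + sHat[recS], fit@records$id, mean)
  expect_equal(pc$yc, as.numeric(manual[pc$id]))
})

test_that("pre-correction is invariant to constant shifts within classes", {
  set.seed(13)
  ns <- 25; k <- 8
  sires <- sprintf("S%02d", 1:ns)
  daughters <- sprintf("D%03d", 1:(ns * k))
  ped <- Pedigree(id = c(sires, daughters),
                  sire = c(rep(NA, ns), rep(sires, each = k)),
                  dam = rep(NA, ns + ns * k))
  herd <- sample.int(4, ns * k, TRUE)
  rec <- data.frame(id = daughters, stage = "heifer", parity = 1,
                    herd = herd, ym = 1, ageIns = 400, ageCalv = NA_real_,
                    IFL = rnorm(ns * k, 25, 4), NINS = 2, ICF = NA_real_,
                    censored = FALSE, stringsAsFactors = FALSE)
  rec2 <- rec
  rec2$IFL <- rec2$IFL + 50 * (herd == 2)  # constant shift in one herd
  pc1 <- precorrect(fitSireModel(rec, ped, stage = "heifer"))
  pc2 <- precorrect(fitSireModel(rec2, ped, stage = "heifer"))
  expect_equal(pc1$yc, pc2$yc, tolerance = 1e-6)
})
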