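# Independent oracle: constrained eigenvalues from the generalized
# eigenproblem formulation -- eigen decomposition of the projected
# cross-product matrix -- rather than the QR + SVD path the package uses.
bruteCcaEig <- function(Y, X, Z = NULL) {
  Y <- t(Y)  # to samples x OTUs
  N <- sum(Y); P <- Y / N
  r <- rowSums(P); cc <- colSums(P)
  Q <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  wcenter <- function(M) sweep(M, 2, colSums(M * r), "-") * sqrt(r)
  proj <- function(A, B) A %*% solve(crossprod(A), crossprod(A, B))
  W <- wcenter(X)
  if (!is.null(Z)) {
    Wz <- wcenter(Z)
    Q <- Q - proj(Wz, Q)
    W <- W - proj(Wz, W)
  }
  Qfit <- proj(W, Q)
  ev <- eigen(tcrossprod(Qfit), symmetric = TRUE)$values
  ev[ev > max(ev, 1e-14) * 1e-10]
}

mdFor <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    sample_id = paste0("s", seq_len(n)),
    grp = sample(rep(c("a", "b"), length.out = n)),
    bin = sample(rep(c("u", "v"), length.out = n)),
    xx = rnorm(n), stringsAsFactors = FALSE))
}

test_that("constraint preparation drops sparse variables and encodes the rest", {
  md <- mdFor(10, seed = 2)
  md$sparse <- c(rep(NA, 3), rnorm(7))   # 30% missing, above the 20% bar
  md$xx[2] <- NA                          # 10% missing, below the bar
  cm <- prepareConstraints(md, c("grp", "xx", "sparse"))
  expect_named(cm$dropped_variables, "sparse")
  expect_equal(unname(cm$dropped_variables), 0.3)
  expect_equal(cm$dropped_samples, "s2")
  expect_equal(sum(cm$matrix[, "xx"]), 0, tolerance = 1e-12)  # centered
  expect_true("grpb" %in% colnames(cm$matrix))                # k-1 indicators
  expect_equal(sum(cm$assign == "grp"), 1L)
  expect_error(prepareConstraints(md, "nope"), "nope")
})

test_that("CA total inertia equals Pearson chi-square over the grand total", {
  diag2 <- matrix(c(10, 0, 0, 10), 2, 2, dimnames = list(c("o1", "o2"), c("s1", "s2")))
  expect_equal(unname(inertia(runCA(diag2))["total"]), 1)
  # independence structure carries no inertia
  rank1 <- outer(c(2, 3, 5), c(1, 2, 4))
  dimnames(rank1) <- list(paste0("o", 1:3), paste0("s", 1:3))
  expect_lt(inertia(runCA(rank1))["total"], 1e-12)
  for (seed in 1:6) {
    Y <- withr::with_seed(seed, matrix(rpois(20, 6) + 1, 5, 4,
                                       dimnames = list(paste0("o", 1:5), paste0("s", 1:4))))
    chi2 <- suppressWarnings(stats::chisq.test(t(Y))$statistic)
    expect_equal(unname(inertia(runCA(Y))["total"]), unname(chi2) / sum(Y),
                 tolerance = 1e-10)
  }
  bad <- matrix(c(1, 0, 2, 0), 2, 2, dimnames = list(c("a", "zero"), c("s1", "s2")))
  expect_error(runCA(bad), "zero")
})

test_that("CCA eigenvalues match the generalized-eigenproblem oracle", {
  for (seed in 1:6) {
    n <- 10; m <- 6
    Y <- withr::with_seed(seed, matrix(rpois(n * m, 5) + 1, m, n,
                                       dimnames = list(paste0("o", 1:m), paste0("s", 1:n))))
    md <- mdFor(n, seed = seed + 100)
    cm <- prepareConstraints(md, "grp")
    fit <- runCCA(Y, cm)
    oracle <- bruteCcaEig(Y, cm$matrix)
    expect_equal(eigenvalues(fit)$constrained, oracle, tolerance = 1e-8)
    # with a condition
    cmx <- prepareConstraints(md, "xx")
    pfit <- runCCA(Y, cm, conditions = cmx)
    poracle <- bruteCcaEig(Y, cm$matrix, cmx$matrix)
    expect_equal(eigenvalues(pfit)$constrained, poracle, tolerance = 1e-8)
  }
})

test_that("CCA agrees with vegan on inertia decomposition and eigenvalues", {
  Y <- withr::with_seed(3, matrix(rpois(12 * 30, 5) + 1, 30, 12,
                                  dimnames = list(paste0("o", 1:30), paste0("s", 1:12))))
  md <- mdFor(12, seed = 5)
  cm <- prepareConstraints(md, c("grp", "xx"))
  fit <- runCCA(Y, cm)
  v <- vegan::cca(t(Y) ~ grp + xx, data = md)
  expect_equal(unname(inertia(fit)["total"]), v$tot.chi, tolerance = 1e-10)
  expect_equal(unname(inertia(fit)["constrained"]), v$CCA$tot.chi, tolerance = 1e-10)
  expect_equal(eigenvalues(fit)$constrained, unname(v$CCA$eig), tolerance = 1e-10)
  expect_equal(eigenvalues(fit)$unconstrained, unname(v$CA$eig), tolerance = 1e-10)
  pv <- vegan::cca(t(Y) ~ xx + Condition(grp), data = md)
  pfit <- runCCA(Y, prepareConstraints(md, "xx"),
                 conditions = prepareConstraints(md, "grp"))
  expect_equal(unname(inertia(pfit)["conditioned"]), pv$pCCA$tot.chi, tolerance = 1e-10)
  expect_equal(unname(inertia(pfit)["constrained"]), pv$CCA$tot.chi, tolerance = 1e-10)
})

test_that("the inertia decomposition identity holds on every fit", {
  for (seed in 1:6) {
    Y <- withr::with_seed(seed, matrix(rpois(14 * 25, 4) + 1, 25, 14,
                                       dimnames = list(paste0("o", 1:25), paste0("s", 1:14))))
    md <- mdFor(14, seed = seed)
    fit <- runCCA(Y, prepareConstraints(md, c("grp", "xx")),
                  conditions = prepareConstraints(md, "bin"))
    i <- inertia(fit)
    expect_equal(i[["total"]],
                 i[["conditioned"]] + i[["constrained"]] + i[["residual"]],
                 tolerance = 1e-8 * i[["total"]])
    expect_true(all(diff(eigenvalues(fit)$constrained) <= 1e-12))
    expect_true(all(eigenvalues(fit)$constrained >= 0))
    expect_equal(i[["constrained"]], sum(eigenvalues(fit)$constrained),
                 tolerance = 1e-10)
  }
})

test_that("CCA with saturated constraints reproduces CA", {
  Y <- withr::with_seed(8, matrix(rpois(8 * 15, 5) + 1, 15, 8,
                                  dimnames = list(paste0("o", 1:15), paste0("s", 1:8))))
  md <- data.frame(sample_id = paste0("s", 1:8),
                   id = factor(paste0("s", 1:8)), stringsAsFactors = FALSE)
  sat <- runCCA(Y, prepareConstraints(md, "id"))
  ca <- runCA(Y)
  expect_equal(unname(inertia(sat)["constrained"]), unname(inertia(ca)["total"]),
               tolerance = 1e-10)
  expect_equal(unname(inertia(sat)["residual"]), 0, tolerance = 1e-10)
  expect_equal(eigenvalues(sat)$constrained, eigenvalues(ca)$unconstrained,
               tolerance = 1e-8)
})

test_that("degenerate constraints are rejected, aliased ones identified", {
  Y <- withr::with_seed(2, matrix(rpois(60, 5) + 1, 10, 6,
                                  dimnames = list(paste0("o", 1:10), paste0("s", 1:6))))
  md <- mdFor(6, seed = 3)
  md$const <- 1
  expect_error(runCCA(Y, prepareConstraints(md, "const")), "zero rank")
  md$dup <- md$xx
  expect_error(runCCA(Y, prepareConstraints(md, c("xx", "dup"))), "aliased")
  fit <- runCCA(Y, prepareConstraints(md, c("xx", "dup")), allow_aliased = TRUE)
  fit1 <- runCCA(Y, prepareConstraints(md, "xx"))
  expect_equal(inertia(fit), inertia(fit1), tolerance = 1e-10)
})

test_that("VIF follows its closed form and flags exact collinearity", {
  ortho <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(ortho)), c(1, 1))
  # two standardized columns with correlation 0.8: VIF = 1/(1-0.64)
  withr::with_seed(10, {
    x <- rnorm(200)
    y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(200)
  })
  x <- (x - mean(x)) / sd(x); y <- (y - mean(y)) / sd(y)
  robs <- cor(x, y)
  expect_equal(unname(vif(cbind(x, y))), rep(1 / (1 - robs^2), 2), tolerance = 1e-8)
  dup <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_true(all(is.infinite(vif(dup))))
})

test_that("weighted VIF matches vegan's CCA diagnostics", {
  Y <- withr::with_seed(6, matrix(rpois(12 * 30, 5) + 1, 30, 12,
                                  dimnames = list(paste0("o", 1:30), paste0("s", 1:12))))
  md <- mdFor(12, seed = 7)
  cm <- prepareConstraints(md, c("grp", "xx"))
  r <- colSums(Y) / sum(Y)
  v <- vegan::cca(t(Y) ~ grp + xx, data = md)
  expect_equal(unname(vif(cm, weights = r)), unname(vegan::vif.cca(v)),
               tolerance = 1e-8)
})

test_that("permutation test is extreme on a planted split and bounded below", {
  Y <- withr::with_seed(9, rbind(
    cbind(matrix(rpois(30, 50), 5, 6), matrix(rpois(30, 1), 5, 6)),
    cbind(matrix(rpois(30, 1), 5, 6), matrix(rpois(30, 50), 5, 6))))
  dimnames(Y) <- list(paste0("o", 1:10), paste0("s", 1:12))
  md <- data.frame(sample_id = paste0("s", 1:12),
                   g = rep(c("hi", "lo"), each = 6), stringsAsFactors = FALSE)
  pt <- permutationTest(Y, prepareConstraints(md, "g"), n_perm = 199, seed = 5)
  expect_equal(pt$p_value, 1 / 200)
  expect_gte(pt$p_value, 1 / (pt$n_perm + 1))
  expect_error(permutationTest(Y, prepareConstraints(md, "g"), n_perm = 10),
               "at least 19")
})

test_that("variance partitioning separates a driving factor from a noise factor", {
  # community driven by factor A only; B is pure noise
  withr::with_seed(14, {
    n <- 24
    A <- rep(c("a1", "a2"), each = n / 2)
    B <- sample(rep(c("b1", "b2"), n / 2))
    mu <- matrix(3, 30, n)
    mu[1:15, A == "a2"] <- 12
    Y <- matrix(rpois(30 * n, as.vector(mu)), 30, n,
                dimnames = list(paste0("o", 1:30), paste0("s", 1:n)))
  })
  md <- data.frame(sample_id = paste0("s", 1:24), A = A, B = B,
                   stringsAsFactors = FALSE)
  vp <- variancePartition(Y, md, c("A", "B"), n_perm = 199, seed = 3)
  shareA <- vp$share_pct[vp$variable == "A"]
  shareB <- vp$share_pct[vp$variable == "B"]
  expect_gte(shareA, 5 * shareB)
  expect_lte(vp$p_value[vp$variable == "A"], 0.005)
  expect_gt(vp$p_value[vp$variable == "B"], 0.05)
  # shares of (near-)orthogonal factors are bounded by the joint model
  expect_lte(shareA + shareB,
             attr(vp, "joint_share_pct") + 1e-6)
})

test_that("sequential partitioning sums to the joint constrained share", {
  Y <- withr::with_seed(16, matrix(rpois(25 * 16, 4) + 1, 25, 16,
                                   dimnames = list(paste0("o", 1:25), paste0("s", 1:16))))
  md <- mdFor(16, seed = 17)
  vp <- variancePartition(Y, md, c("grp", "xx"), n_perm = 39, seed = 2,
                          scheme = "sequential")
  expect_equal(sum(vp$share_pct), attr(vp, "joint_share_pct"), tolerance = 1e-8)
})

test_that("Hellinger and raw runs rank variable shares consistently", {
  st <- generateStudy(smallStudyConfig(seed = 6))
  tab <- filterRare(st$table)
  vars <- c("plant_label", "pH")
  raw <- variancePartition(tab, st$metadata, vars, n_perm = 39, seed = 4)
  hel <- variancePartition(hellinger(tab), st$metadata, vars, n_perm = 39, seed = 4)
  expect_equal(raw$variable[which.max(raw$share_pct)],
               hel$variable[which.max(hel$share_pct)])
})
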