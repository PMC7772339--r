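## Correspondence analysis and (partial) canonical correspondence analysis,
## implemented from the chi-square standardized residual matrix
##   Q = D_r^{-1/2} (P - r c') D_c^{-1/2},  P = Y / sum(Y)
## with r, c the row (sample) and column (OTU) mass vectors. Total inertia is
## ||Q||_F^2 = Pearson chi-square of the table divided by its grand total.
## Constrained analysis projects the rows of Q onto the span of the
## weighted, centered constraint matrix; partialling removes the span of the
## conditioning variables from both Q and the constraints first. The
## Frobenius decomposition conditioned + constrained + residual = total is
## exact by orthogonality of the projections.

.EIG_TOL <- 1e-12

.caCore <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("community matrix must be non-negative")
  N <- sum(Y)
  if (N <= 0) stop("community matrix has zero grand total")
  zr <- rowSums(Y) == 0
  zc <- colSums(Y) == 0
  if (any(zr)) stop("all-zero sample(s): ", paste(rownames(Y)[zr], collapse = ", "))
  if (any(zc)) stop("all-zero OTU(s): ", paste(colnames(Y)[zc], collapse = ", "))
  P <- Y / N
  r <- rowSums(P)
  cc <- colSums(P)
  Q <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  list(Q = Q, r = r, c = cc, N = N)
}

# community input: OtuTable (counts, transposed to samples x OTUs) or a
# matrix interpreted as OTUs x samples (e.g. a Hellinger-transformed table)
.communityMatrix <- function(x) {
  if (is(x, "OtuTable")) t(counts(x)) else t(as.matrix(x))
}

.eigTrim <- function(d2) {
  if (!length(d2)) return(numeric())
  d2[d2 > max(d2[1], .EIG_TOL) * .EIG_TOL]
}

#' Prepare an ordination constraint matrix from sample metadata
#'
#' Variables with a missing-value fraction above `max_missing_fraction` are
#' dropped (and reported); remaining samples with any residual missing value
#' are removed. Categorical variables are expanded to treatment-coded
#' indicator columns (first level as reference); continuous variables are
#' centered. The string `"unknown"` counts as missing.
#'
#' @param metadata sample metadata `data.frame` with `sample_id` rows.
#' @param variables column names to use as constraints.
#' @param max_missing_fraction drop a variable when more than this fraction
#'   of samples lacks it (default 0.2).
#' @return list of class `ConstraintMatrix`: `matrix` (samples x columns),
#'   `sample_ids`, `assign` (variable of origin per column),
#'   `dropped_variables` (with their missing fractions), `dropped_samples`.
#' @export
prepareConstraints <- function(metadata, variables, max_missing_fraction = 0.2) {
  miss <- setdiff(variables, colnames(metadata))
  if (length(miss)) stop("variable(s) not in metadata: ", paste(miss, collapse = ", "))
  ids <- if ("sample_id" %in% colnames(metadata)) metadata$sample_id else rownames(metadata)
  isMissing <- function(v) is.na(v) | (is.character(v) & v == "unknown")
  fracMiss <- vapply(variables, function(v) mean(isMissing(metadata[[v]])), numeric(1))
  droppedVars <- fracMiss[fracMiss > max_missing_fraction]
  keepVars <- names(fracMiss)[fracMiss <= max_missing_fraction]
  if (!length(keepVars)) stop("no constraint variable survives the missingness filter")
  sub <- metadata[, keepVars, drop = FALSE]
  rowBad <- Reduce(`|`, lapply(keepVars, function(v) isMissing(sub[[v]])))
  droppedSamples <- ids[rowBad]
  sub <- sub[!rowBad, , drop = FALSE]
  ids <- ids[!rowBad]
  cols <- list(); assign <- character()
  for (v in keepVars) {
    val <- sub[[v]]
    if (is.numeric(val)) {
      m <- matrix(val - mean(val), ncol = 1, dimnames = list(NULL, v))
    } else {
      f <- factor(val)
      if (nlevels(f) < 2L) {
        m <- matrix(numeric(0), nrow = length(val), ncol = 0)
      } else {
        m <- stats::model.matrix(~f)[, -1L, drop = FALSE]
        colnames(m) <- paste0(v, levels(f)[-1L])
      }
    }
    if (ncol(m)) {
      cols[[v]] <- m
      assign <- c(assign, rep(v, ncol(m)))
    }
  }
  if (!length(cols)) stop("no usable constraint columns (all variables constant?)")
  mat <- do.call(cbind, cols)
  rownames(mat) <- ids
  structure(list(matrix = mat, sample_ids = ids, assign = assign,
                 variables = keepVars,
                 dropped_variables = droppedVars,
                 dropped_samples = droppedSamples),
            class = "ConstraintMatrix")
}

.newOrdinationResult <- function(total, cond, constr, resid, eigC, eigU,
                                 site, species, biplot, n, m) {
  new("OrdinationResult",
      totalInertia = total, conditionedInertia = cond,
      constrainedInertia = constr, residualInertia = resid,
      eigConstrained = eigC, eigUnconstrained = eigU,
      siteScores = site, speciesScores = species, biplotScores = biplot,
      nSamples = as.integer(n), nOtus = as.integer(m))
}

#' Correspondence analysis
#'
#' Unconstrained CA of a community table via singular value decomposition of
#' the chi-square standardized residual matrix. Total inertia equals the
#' Pearson chi-square statistic of the table divided by its grand total.
#'
#' @param x an [OtuTable-class] or a non-negative matrix (OTUs x samples,
#'   e.g. a Hellinger-transformed table). No all-zero rows or columns.
#' @return an [OrdinationResult-class] with all axes unconstrained.
#' @export
runCA <- function(x) {
  Y <- .communityMatrix(x)
  core <- .caCore(Y)
  sv <- svd(core$Q)
  eig <- .eigTrim(sv$d^2)
  k <- length(eig)
  axNames <- if (k > 0) paste0("CA", seq_len(k)) else NULL
  site <- matrix(0, nrow(Y), k, dimnames = list(rownames(Y), axNames))
  species <- matrix(0, ncol(Y), k, dimnames = list(colnames(Y), axNames))
  if (k > 0) {
    site[] <- sweep(sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k),
                    1L, sqrt(core$r), "/")
    species[] <- sweep(sv$v[, seq_len(k), drop = FALSE], 1L, sqrt(core$c), "/")
  }
  .newOrdinationResult(sum(core$Q^2), 0, 0, sum(core$Q^2),
                       numeric(), eig, site, species,
                       matrix(numeric(), 0, 0), nrow(Y), ncol(Y))
}

.alignConstraints <- function(ids, constraints) {
  if (!inherits(constraints, "ConstraintMatrix")) {
    stop("'constraints' must come from prepareConstraints()")
  }
  common <- intersect(ids, constraints$sample_ids)
  if (length(common) < 2L) stop("fewer than two samples shared by table and constraints")
  list(ids = common,
       X = constraints$matrix[match(common, constraints$sample_ids), , drop = FALSE],
       assign = constraints$assign)
}

# weighted centering + sqrt-mass row scaling, the coordinate system in which
# ordinary least squares on Q is the correct row-mass-weighted regression
.weightedDesign <- function(X, r) {
  Xc <- sweep(X, 2L, colSums(X * r), "-")
  sweep(Xc, 1L, sqrt(r), "*")
}

#' Canonical correspondence analysis, optionally partial
#'
#' Projects the chi-square standardized community matrix onto the span of the
#' (row-mass weighted, centered) constraint columns; the fitted part is
#' decomposed into constrained axes and the remainder into unconstrained
#' axes. With `conditions`, the variation explained by the conditioning
#' variables is removed from both the community matrix and the constraints
#' first (partial CCA), and reported as conditioned inertia.
#'
#' @param x an [OtuTable-class] or non-negative matrix (OTUs x samples).
#' @param constraints a `ConstraintMatrix` from [prepareConstraints()].
#' @param conditions optional `ConstraintMatrix` of conditioning variables.
#' @param allow_aliased drop exactly collinear (aliased) constraint columns
#'   instead of raising an error. Structural aliasing is common in nested
#'   survey designs (e.g. a reference-fraction indicator implied by the
#'   plant-label indicators); the aliased projection contributes nothing to
#'   the fitted space, so dropping is exact.
#' @return an [OrdinationResult-class]; `conditioned + constrained +
#'   residual = total` holds to 1e-8 relative.
#' @export
runCCA <- function(x, constraints, conditions = NULL, allow_aliased = FALSE) {
  Yfull <- .communityMatrix(x)
  al <- .alignConstraints(rownames(Yfull), constraints)
  ids <- al$ids
  if (!is.null(conditions)) {
    alc <- .alignConstraints(ids, conditions)
    ids <- alc$ids
  }
  Y <- Yfull[ids, , drop = FALSE]
  Y <- Y[, colSums(Y) > 0, drop = FALSE]
  core <- .caCore(Y)
  Q <- core$Q
  total <- sum(Q^2)
  X <- al$X[match(ids, al$ids), , drop = FALSE]
  W <- .weightedDesign(X, core$r)
  cond <- 0
  pcond <- 0L
  if (!is.null(conditions)) {
    Z <- alc$X[match(ids, alc$ids), , drop = FALSE]
    Wz <- .weightedDesign(Z, core$r)
    qz <- qr(Wz)
    pcond <- qz$rank
    Qc <- qr.fitted(qz, Q)
    cond <- sum(Qc^2)
    Q <- Q - Qc
    W <- W - qr.fitted(qz, W)
  }
  qx <- qr(W)
  if (qx$rank == 0L) {
    stop("constraints have zero rank after centering",
         if (!is.null(conditions)) " and conditioning" else "")
  }
  aliased <- character()
  if (qx$rank < ncol(W)) {
    aliased <- colnames(W)[qx$pivot[(qx$rank + 1L):ncol(W)]]
    if (!allow_aliased) {
      stop("collinear (aliased) constraint column(s): ",
           paste(aliased, collapse = ", "))
    }
  }
  Qfit <- qr.fitted(qx, Q)
  Qres <- Q - Qfit
  constr <- sum(Qfit^2)
  resid <- sum(Qres^2)
  svf <- svd(Qfit)
  eigC <- .eigTrim(svf$d^2)
  kC <- length(eigC)
  svr <- svd(Qres)
  eigU <- .eigTrim(svr$d^2)
  site <- if (kC) {
    s <- sweep(svf$u[, seq_len(kC), drop = FALSE] %*% diag(svf$d[seq_len(kC)], kC),
               1L, sqrt(core$r), "/")
    dimnames(s) <- list(ids, paste0("CCA", seq_len(kC)))
    s
  } else matrix(numeric(), length(ids), 0)
  species <- if (kC) {
    sp <- sweep(svf$v[, seq_len(kC), drop = FALSE], 1L, sqrt(core$c), "/")
    dimnames(sp) <- list(colnames(Y), paste0("CCA", seq_len(kC)))
    sp
  } else matrix(numeric(), ncol(Y), 0)
  biplot <- if (kC) {
    nrm <- sqrt(colSums(W^2))
    nrm[nrm < 1e-12] <- Inf  # aliased columns score zero
    Wn <- sweep(W, 2L, nrm, "/")
    b <- crossprod(Wn, svf$u[, seq_len(kC), drop = FALSE])
    colnames(b) <- paste0("CCA", seq_len(kC))
    b
  } else matrix(numeric(), 0, 0)
  .newOrdinationResult(total, cond, constr, resid, eigC, eigU,
                       site, species, biplot, length(ids), ncol(Y))
}

#' Variance inflation factors of constraint columns
#'
#' `VIF_j = 1 / (1 - R2_j)` from the weighted regression of column `j` on
#' all other columns (with intercept). Exactly collinear columns are
#' reported as `Inf`.
#'
#' @param constraints `ConstraintMatrix` or plain numeric matrix.
#' @param weights row weights (e.g. CCA row masses); uniform if `NULL`.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(constraints, weights = NULL) {
  X <- if (inherits(constraints, "ConstraintMatrix")) constraints$matrix else as.matrix(constraints)
  if (ncol(X) < 2L) stop("need at least two constraint columns for VIF")
  if (is.null(weights)) weights <- rep(1 / nrow(X), nrow(X))
  weights <- weights / sum(weights)
  out <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    sw <- sqrt(weights)
    fit <- qr(sw * Z)
    res <- qr.resid(fit, sw * y)
    ybar <- sum(weights * y)
    tss <- sum(weights * (y - ybar)^2)
    if (tss <= 0) return(Inf)
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

# Internal machinery shared by permutationTest: pre-computes the pieces of a
# (partial) CCA fit so each permutation costs two projections.
.ccaEngine <- function(x, constraints, conditions = NULL) {
  Yfull <- .communityMatrix(x)
  al <- .alignConstraints(rownames(Yfull), constraints)
  ids <- al$ids
  alc <- NULL
  if (!is.null(conditions)) {
    alc <- .alignConstraints(ids, conditions)
    ids <- alc$ids
  }
  Y <- Yfull[ids, , drop = FALSE]
  Y <- Y[, colSums(Y) > 0, drop = FALSE]
  core <- .caCore(Y)
  Q <- core$Q
  W <- .weightedDesign(al$X[match(ids, al$ids), , drop = FALSE], core$r)
  qz <- NULL
  pcond <- 0L
  if (!is.null(alc)) {
    Wz <- .weightedDesign(alc$X[match(ids, alc$ids), , drop = FALSE], core$r)
    qz <- qr(Wz)
    pcond <- qz$rank
    Q <- Q - qr.fitted(qz, Q)
    W <- W - qr.fitted(qz, W)
  }
  qx <- qr(W)
  list(Qr = Q, qx = qx, qz = qz, q = qx$rank, pcond = pcond,
       n = length(ids), total = sum(core$Q^2))
}

.ccaStat <- function(eng, Qr) {
  fit <- qr.fitted(eng$qx, Qr)
  constr <- sum(fit^2)
  resid <- sum(Qr^2) - constr
  dfres <- eng$n - eng$q - eng$pcond - 1L
  list(constr = constr, resid = resid,
       F = (constr / eng$q) / (resid / dfres))
}

#' Permutation test for (partial) CCA
#'
#' Pseudo-F test of the constrained inertia:
#' `F = (constrained/q) / (residual/(n - q - p_cond - 1))` with `q` the
#' constraint rank and `p_cond` the rank of the conditions. The null
#' distribution permutes sample rows of the chi-square standardized matrix
#' (free permutation without conditions; permutation of the residuals of the
#' conditioned model otherwise, the reduced-model scheme), and
#' `p = (1 + #(F* >= F)) / (n_perm + 1)`.
#'
#' @inheritParams runCCA
#' @param n_perm number of permutations (>= 19; default 999).
#' @param seed optional RNG seed for the permutations.
#' @return list: `pseudo_F`, `p_value`, `n_perm`, `constrained`, `residual`.
#' @export
permutationTest <- function(x, constraints, conditions = NULL, n_perm = 999,
                            seed = NULL) {
  if (n_perm < 19) stop("n_perm must be at least 19 (p-value resolution)")
  eng <- .ccaEngine(x, constraints, conditions)
  obs <- .ccaStat(eng, eng$Qr)
  run <- function() {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      Qp <- eng$Qr[sample.int(eng$n), , drop = FALSE]
      if (!is.null(eng$qz)) Qp <- Qp - qr.fitted(eng$qz, Qp)
      if (.ccaStat(eng, Qp)$F >= obs$F - 1e-12) exceed <- exceed + 1L
    }
    (1 + exceed) / (n_perm + 1)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(pseudo_F = obs$F, p_value = p, n_perm = as.integer(n_perm),
       constrained = obs$constr, residual = obs$resid)
}

#' Per-variable variance partitioning by partial CCA
#'
#' For each variable the marginal-partial share: the constrained inertia of
#' the partial CCA with that variable as the only constraint and all other
#' variables (plus any scope conditions) as conditions, expressed as percent
#' of total inertia, with a reduced-model permutation p-value. Marginal
#' shares of correlated variables do not sum to the joint constrained
#' inertia; the sequential (Type-I, order-dependent) decomposition is
#' available via `scheme = "sequential"`.
#'
#' @param x an [OtuTable-class] or matrix (OTUs x samples).
#' @param metadata sample metadata.
#' @param variables metadata columns to partition over.
#' @param scope_conditions optional extra metadata columns conditioned out of
#'   every fit (e.g. area/subsite for spatial autocorrelation).
#' @param n_perm permutations per variable (default 199).
#' @param seed RNG seed for the permutations.
#' @param scheme `"marginal"` (default) or `"sequential"`.
#' @param max_missing_fraction passed to [prepareConstraints()].
#' @return `data.frame` (one row per variable): `variable`, `share_pct`,
#'   `pseudo_F`, `p_value`, `n_perm`; attributes `total_inertia`,
#'   `joint_constrained`, `joint_share_pct`, `scheme`.
#' @export
variancePartition <- function(x, metadata, variables, scope_conditions = NULL,
                              n_perm = 199, seed = NULL,
                              scheme = c("marginal", "sequential"),
                              max_missing_fraction = 0.2) {
  scheme <- match.arg(scheme)
  allVars <- c(variables, scope_conditions)
  cm <- prepareConstraints(metadata, allVars, max_missing_fraction)
  kept <- intersect(variables, cm$variables)
  if (!length(kept)) stop("no partition variable survives preparation")
  condVars <- intersect(scope_conditions, cm$variables)
  subMat <- function(vars) {
    keep <- cm$assign %in% vars
    structure(list(matrix = cm$matrix[, keep, drop = FALSE],
                   sample_ids = cm$sample_ids,
                   assign = cm$assign[keep], variables = vars,
                   dropped_variables = numeric(), dropped_samples = character()),
              class = "ConstraintMatrix")
  }
  condOf <- function(vars) if (length(vars)) subMat(vars) else NULL
  joint <- runCCA(x, subMat(kept), condOf(condVars), allow_aliased = TRUE)
  seeds <- if (is.null(seed)) vector("list", length(kept)) else
    as.list(seed + seq_along(kept))
  rows <- lapply(seq_along(kept), function(i) {
    v <- kept[i]
    others <- c(setdiff(kept, v), condVars)
    fit <- runCCA(x, subMat(v), condOf(others), allow_aliased = TRUE)
    pt <- permutationTest(x, subMat(v), condOf(others), n_perm = n_perm,
                          seed = seeds[[i]])
    share <- if (scheme == "marginal") {
      100 * fit@constrainedInertia / fit@totalInertia
    } else NA_real_
    data.frame(variable = v, share_pct = share, pseudo_F = pt$pseudo_F,
               p_value = pt$p_value, n_perm = pt$n_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (scheme == "sequential") {
    prev <- character()
    for (i in seq_along(kept)) {
      fit <- runCCA(x, subMat(kept[i]), condOf(c(prev, condVars)),
                    allow_aliased = TRUE)
      out$share_pct[i] <- 100 * fit@constrainedInertia / fit@totalInertia
      prev <- c(prev, kept[i])
    }
  }
  rownames(out) <- NULL
  attr(out, "total_inertia") <- joint@totalInertia
  attr(out, "joint_constrained") <- joint@constrainedInertia
  attr(out, "joint_share_pct") <- 100 * joint@constrainedInertia / joint@totalInertia
  attr(out, "conditioned_share_pct") <- 100 * joint@conditionedInertia / joint@totalInertia
  attr(out, "scheme") <- scheme
  out
}

## ---- OrdinationResult methods ------------------------------------------

#' @rdname OrdinationResult-class
#' @param x,object an `OrdinationResult`.
#' @export
setMethod("inertia", "OrdinationResult", function(x) {
  c(total = x@totalInertia, conditioned = x@conditionedInertia,
    constrained = x@constrainedInertia, residual = x@residualInertia)
})

#' @rdname OrdinationResult-class
#' @export
setMethod("eigenvalues", "OrdinationResult", function(x) {
  list(constrained = x@eigConstrained, unconstrained = x@eigUnconstrained)
})

#' @rdname OrdinationResult-class
#' @export
setMethod("siteScores", "OrdinationResult", function(x) x@siteScores)

#' @rdname OrdinationResult-class
#' @export
setMethod("speciesScores", "OrdinationResult", function(x) x@speciesScores)

setMethod("show", "OrdinationResult", function(object) {
  i <- inertia(object)
  cat("OrdinationResult: ", object@nSamples, " samples x ", object@nOtus,
      " OTUs\n", sep = "")
  cat(sprintf("  inertia  total %.4f | conditioned %.4f (%.1f%%) | constrained %.4f (%.1f%%) | residual %.4f\n",
              i["total"], i["conditioned"], 100 * i["conditioned"] / i["total"],
              i["constrained"], 100 * i["constrained"] / i["total"], i["residual"]))
  if (length(object@eigConstrained)) {
    cat("  constrained eigenvalues:",
        paste(signif(utils::head(object@eigConstrained, 4), 4), collapse = ", "),
        if (length(object@eigConstrained) > 4) "...", "\n")
  }
})
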