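# --- internal matrix core ---------------------------------------------------

# Reshape long (subject, condition, channel, time, value) data into
# subject-by-cell matrices per condition plus the cell key.
pls_blocks <- function(data) {
  stopifnot(all(c("subject", "condition", "value") %in% names(data)))
  cell_cols <- setdiff(names(data), c("subject", "condition", "value"))
  if (length(cell_cols) == 0) stop("no measure columns to identify cells",
                                   call. = FALSE)
  wide <- tidyr::pivot_wider(
    data,
    id_cols = dplyr::all_of(c("subject", "condition")),
    names_from = dplyr::all_of(cell_cols),
    values_from = "value")
  subjects <- unique(wide$subject)
  conditions <- unique(wide$condition)
  if (length(subjects) < 2 || length(conditions) < 2) {
    stop("PLS requires >= 2 subjects and >= 2 conditions", call. = FALSE)
  }
  X <- as.matrix(wide[setdiff(names(wide), c("subject", "condition"))])
  list(X = X, subject = wide$subject, condition = wide$condition,
       subjects = subjects, conditions = conditions,
       cells = setdiff(names(wide), c("subject", "condition")))
}

# Cross-block covariance between a deviation-coded condition design and the
# measures, followed by SVD. Rows of X are subject-condition means.
pls_svd <- function(X, condition, conditions) {
  Y <- outer(condition, conditions, `==`) * 1
  Y <- sweep(Y, 1, rowMeans(Y))             # deviation coding
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Y, Xc) / nrow(X)
  sv <- svd(C)
  list(d = sv$d, saliences = sv$v, lv_design = sv$u, C = C)
}

permute_within_subject <- function(condition, subject) {
  out <- condition
  for (s in unique(subject)) {
    idx <- which(subject == s)
    out[idx] <- condition[idx][sample(length(idx))]
  }
  out
}

# --- exported surface -------------------------------------------------------

#' Partial least squares condition contrast (core SVD)
#'
#' Computes the singular value decomposition of the cross-block covariance
#' between a deviation-coded condition design and per-subject condition means
#' of a multivariate measure (e.g. a channel-by-time surface). Each latent
#' variable (LV) has a singular value (its share of cross-block covariance)
#' and unit-norm saliences, one per measure cell.
#'
#' @param data Long tibble with columns `subject`, `condition`, `value`, and
#'   one or more cell-identifier columns (e.g. `channel`, `time`); one row per
#'   subject-condition-cell mean.
#' @return A `pls_result` object (no inference fields yet; see [pls_task()]).
#' @seealso [pls_permutation()], [pls_bootstrap()], [pls_task()]
#' @export
pls_contrast <- function(data) {
  b <- pls_blocks(data)
  sv <- pls_svd(b$X, b$condition, b$conditions)
  structure(
    list(singular_values = sv$d, saliences = sv$saliences,
         lv_design = sv$lv_design,
         cells = b$cells, conditions = b$conditions,
         n_subjects = length(b$subjects),
         p_perm = NULL, bootstrap_se = NULL, bootstrap_ratio = NULL,
         n_permutations = 0L, n_bootstraps = 0L,
         data = b),
    class = "pls_result"
  )
}

#' Permutation p-values for PLS latent variables
#'
#' Condition labels are re-shuffled within each subject `n_perm` times; each
#' LV's p-value is the add-one estimator
#' `(1 + #permuted singular value >= observed) / (n_perm + 1)`, so p is never
#' zero and is bounded below by `1/(n_perm + 1)`.
#'
#' @param fit A `pls_result` from [pls_contrast()].
#' @param n_perm Number of permutations (default 1000, >= 100).
#' @param seed Integer seed (optional).
#' @return The `pls_result` with `p_perm` and `n_permutations` filled in.
#' @export
pls_permutation <- function(fit, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(fit, "pls_result"), n_perm >= 100)
  b <- fit$data
  obs <- fit$singular_values
  exceed <- integer(length(obs))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      cond_p <- permute_within_subject(b$condition, b$subject)
      d_p <- pls_svd(b$X, cond_p, b$conditions)$d
      exceed <- exceed + (d_p >= obs)
    }
  })
  fit$p_perm <- (1 + exceed) / (n_perm + 1)
  fit$n_permutations <- as.integer(n_perm)
  fit
}

#' Bootstrap salience reliability ratios
#'
#' Subjects are resampled with replacement (conditions kept fixed) `n_boot`
#' times; each resample's saliences are sign-aligned to the observed solution
#' (dot-product sign fix for the SVD sign indeterminacy), and the ratio of the
#' observed salience to its bootstrap standard error is returned per cell per
#' LV -- a metric on the scale of a z-score. Degenerate resamples (a single
#' distinct subject) are skipped and counted.
#'
#' @param fit A `pls_result` from [pls_contrast()].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed (optional).
#' @return The `pls_result` with `bootstrap_se`, `bootstrap_ratio`,
#'   `n_bootstraps` and `n_skipped_resamples` filled in.
#' @export
pls_bootstrap <- function(fit, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(fit, "pls_result"))
  b <- fit$data
  if (length(b$subjects) < 5) {
    stop("bootstrap requires >= 5 subjects", call. = FALSE)
  }
  V <- fit$saliences
  acc <- array(0, dim = c(dim(V), 2))   # running sum and sum of squares
  used <- 0L
  skipped <- 0L
  with_seed(seed, {
    for (i in seq_len(n_boot)) {
      pick <- sample(b$subjects, length(b$subjects), replace = TRUE)
      if (length(unique(pick)) < 2) { skipped <- skipped + 1L; next }
      idx <- unlist(lapply(pick, function(s) which(b$subject == s)))
      sv_b <- pls_svd(b$X[idx, , drop = FALSE], b$condition[idx], b$conditions)
      Vb <- sv_b$saliences[, seq_len(ncol(V)), drop = FALSE]
      sgn <- sign(colSums(Vb * V)); sgn[sgn == 0] <- 1
      Vb <- sweep(Vb, 2, sgn, `*`)
      acc[, , 1] <- acc[, , 1] + Vb
      acc[, , 2] <- acc[, , 2] + Vb^2
      used <- used + 1L
    }
  })
  if (used < 2) stop("too few usable bootstrap resamples", call. = FALSE)
  se <- sqrt(pmax(acc[, , 2] / used - (acc[, , 1] / used)^2, 0)) *
    sqrt(used / (used - 1))
  fit$bootstrap_se <- se
  fit$bootstrap_ratio <- ifelse(se > 0, V / se, Inf * sign(V))
  fit$n_bootstraps <- as.integer(used)
  fit$n_skipped_resamples <- skipped
  fit
}

#' Full PLS condition contrast with permutation and bootstrap inference
#'
#' Convenience wrapper: [pls_contrast()], then [pls_permutation()] and
#' [pls_bootstrap()] with sub-seeds derived from `seed`.
#'
#' @inheritParams pls_contrast
#' @param n_perm,n_boot Resampling counts (defaults 1000 each).
#' @param seed Integer seed for both procedures (optional).
#' @return A complete `pls_result`.
#' @export
pls_task <- function(data, n_perm = 1000, n_boot = 1000, seed = NULL) {
  fit <- pls_contrast(data)
  fit <- pls_permutation(fit, n_perm = n_perm, seed = derive_seed(seed, 1))
  pls_bootstrap(fit, n_boot = n_boot, seed = derive_seed(seed, 2))
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %d LV(s), %d subjects, %d conditions\n",
              length(x$singular_values), x$n_subjects, length(x$conditions)))
  print(glance(x))
  invisible(x)
}

#' @export
glance.pls_result <- function(x, ...) {
  d2 <- x$singular_values^2
  tibble::tibble(
    lv = seq_along(x$singular_values),
    singular_value = x$singular_values,
    prop_covariance = d2 / sum(d2),
    p_perm = if (is.null(x$p_perm)) NA_real_ else x$p_perm,
    n_permutations = x$n_permutations,
    n_bootstraps = x$n_bootstraps
  )
}

#' @export
tidy.pls_result <- function(x, ...) {
  n_lv <- length(x$singular_values)
  out <- tibble::tibble(
    cell = rep(x$cells, times = n_lv),
    lv = rep(seq_len(n_lv), each = length(x$cells)),
    salience = as.vector(x$saliences[, seq_len(n_lv)])
  )
  if (!is.null(x$bootstrap_se)) {
    out$bootstrap_se <- as.vector(x$bootstrap_se[, seq_len(n_lv)])
    out$bootstrap_ratio <- as.vector(x$bootstrap_ratio[, seq_len(n_lv)])
  }
  out
}
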