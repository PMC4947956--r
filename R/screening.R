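#' Mutant-strain screening matrix
#'
#' Ratings of screened mutant strains over a set of quality indicators;
#' by default four: maximum biomass concentration, butyrate
#' concentration, hydrogen, and butyrate/acetate ratio.
#'
#' @param ratings numeric matrix or data frame, one row per strain, no
#'   missing cells, at least 5 rows and 2 columns.
#' @param strain_id optional character labels (default `strain_1, ...`).
#' @return A list of class `"screening_matrix"` with elements
#'   `strain_id` and `ratings` (numeric matrix).
#' @export
screening_matrix <- function(ratings, strain_id = NULL) {
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings)) abort_validation("ratings must be numeric")
  if (anyNA(ratings)) abort_validation("ratings must have no missing cells")
  if (nrow(ratings) < 5L) abort_validation("need at least 5 strains")
  if (ncol(ratings) < 2L) abort_validation("need at least 2 rating variables")
  if (is.null(strain_id)) strain_id <- paste0("strain_", seq_len(nrow(ratings)))
  if (length(strain_id) != nrow(ratings))
    abort_validation("strain_id length must match the number of rows")
  if (is.null(colnames(ratings)))
    colnames(ratings) <- paste0("rating_", seq_len(ncol(ratings)))
  structure(list(strain_id = as.character(strain_id), ratings = ratings),
            class = "screening_matrix")
}

#' Weighted principal component analysis
#'
#' PCA of a strain rating matrix with per-variable weights. Columns are
#' centered and scaled by the square root of their weight, and the
#' covariance of the scaled data is eigendecomposed. With
#' `"inverse-variance"` weights (the default, appropriate when variables
#' carry different units) this is PCA of the correlation matrix, and the
#' analysis is invariant to per-column changes of unit. The coefficient
#' matrix expressed on the original variables (`loadings_raw`) is not
#' orthonormal because of the weighting; the orthonormalized loadings in
#' the scaled space are exposed as `loadings` and satisfy
#' `t(L) %*% L = I`.
#'
#' @param x a [screening_matrix()] (or bare numeric matrix).
#' @param weights positive per-variable weights, or the string
#'   `"inverse-variance"`.
#' @return An object of class `"wpca"`: `weights`, orthonormal
#'   `loadings`, non-orthonormal `loadings_raw`, non-increasing
#'   `eigenvalues`, per-observation `scores`, column `center`, and
#'   `var_fraction`. Each loading's largest-magnitude element is made
#'   positive (eigenvector signs are arbitrary).
#' @examples
#' m <- gen_screening_matrix(n_strains = 50, seed = 1)
#' pc <- weighted_pca(m)
#' variance_explained(pc, 3)
#' @export
weighted_pca <- function(x, weights = "inverse-variance") {
  if (!inherits(x, "screening_matrix")) x <- screening_matrix(x)
  r <- x$ratings
  p <- ncol(r)
  if (identical(weights, "inverse-variance")) {
    v <- apply(r, 2, stats::var)
    if (any(v == 0))
      abort_validation(paste("zero-variance column with inverse-variance",
                             "weights:", colnames(r)[which(v == 0)[1]]))
    weights <- 1 / v
  }
  if (length(weights) != p || any(weights <= 0))
    abort_validation("weights must be positive, one per rating variable")
  center <- colMeans(r)
  scaled <- sweep(sweep(r, 2, center), 2, sqrt(weights), `*`)
  eg <- eigen(stats::cov(scaled), symmetric = TRUE)
  V <- eg$vectors
  # sign convention: largest-magnitude element of each loading positive
  for (j in seq_len(p)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  lam <- pmax(eg$values, 0)
  rownames(V) <- colnames(r)
  colnames(V) <- paste0("PC", seq_len(p))
  raw <- sweep(V, 1, sqrt(weights), `*`)  # coefficients on original variables
  scores <- scaled %*% V
  rownames(scores) <- x$strain_id
  structure(list(weights = weights, loadings = V, loadings_raw = raw,
                 eigenvalues = lam, scores = scores, center = center,
                 var_fraction = lam / sum(lam), strain_id = x$strain_id),
            class = "wpca")
}

#' @export
print.wpca <- function(x, digits = 4, ...) {
  cat("Weighted PCA of", nrow(x$scores), "strains x",
      nrow(x$loadings), "rating variables\n")
  cat("eigenvalues:", paste(signif(x$eigenvalues, digits), collapse = ", "), "\n")
  cat("variance fractions:",
      paste(signif(x$var_fraction, digits), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.wpca <- function(object, ...) {
  tab <- rbind(eigenvalue = object$eigenvalues,
               `var fraction` = object$var_fraction,
               cumulative = cumsum(object$var_fraction))
  colnames(tab) <- colnames(object$loadings)
  structure(list(table = tab, loadings = object$loadings), class = "summary.wpca")
}

#' @export
print.summary.wpca <- function(x, digits = 4, ...) {
  print(round(x$table, digits))
  cat("\northonormal loadings:\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' @export
predict.wpca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scaled <- sweep(sweep(newdata, 2, object$center), 2,
                  sqrt(object$weights), `*`)
  scaled %*% object$loadings
}

#' Cumulative variance explained
#'
#' Fraction of total (weighted) variance carried by the first `k`
#' principal components.
#'
#' @param model a [weighted_pca()] result.
#' @param k number of leading components, `1 <= k <=` number of variables.
#' @return A fraction in `[0, 1]`, equal to 1 at `k = ncol`.
#' @export
variance_explained <- function(model, k) {
  stopifnot(inherits(model, "wpca"))
  p <- length(model$eigenvalues)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > p || k != round(k))
    abort_validation(sprintf("k must be an integer in 1..%d", p))
  sum(model$var_fraction[seq_len(k)])
}

#' Hotelling's T-squared in principal component space
#'
#' Squared multivariate distance of each observation from the data
#' centre, using the first `k` components scaled by their eigenvalues:
#' `T2_i = sum_{j<=k} score_ij^2 / lambda_j`. Zero exactly when the
#' observation sits at the centre of the retained component space.
#'
#' @param model a [weighted_pca()] result.
#' @param k number of components (default 3).
#' @return Non-negative values, one per observation.
#' @export
hotelling_t2 <- function(model, k = 3) {
  stopifnot(inherits(model, "wpca"))
  if (k < 1 || k > length(model$eigenvalues) || k != round(k))
    abort_validation("k out of range")
  if (any(model$eigenvalues[seq_len(k)] <= 0))
    abort_validation("k exceeds the rank of strictly positive eigenvalues")
  s <- model$scores[, seq_len(k), drop = FALSE]
  drop(s^2 %*% (1 / model$eigenvalues[seq_len(k)]))
}

#' Rank strains by outlyingness
#'
#' Orders strain labels by descending Hotelling's T-squared; ties keep
#' their input order (stable sort).
#'
#' @param t2 per-observation T-squared values.
#' @param strain_id labels, same length as `t2`.
#' @return Character vector of labels, most extreme strain first.
#' @export
rank_outliers <- function(t2, strain_id) {
  if (length(t2) != length(strain_id))
    abort_validation("t2 and strain_id must have equal length")
  as.character(strain_id)[order(-t2)]
}
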