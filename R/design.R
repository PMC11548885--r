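#' Joint response configuration matrix
#'
#' Enumerates the `Q = 2^K` joint configurations of `K` binary endpoints as the
#' rows of a `Q x K` binary matrix `H`. Row 1 is the all-success pattern, row
#' `Q` the all-failure pattern, and rows are sorted in strictly descending
#' binary order (row `q`, read as a K-bit number, decreases with `q`). The
#' all-failure row is the reference category of the multinomial logistic
#' model: its regression coefficients are fixed at zero for identifiability.
#'
#' @param K Number of binary endpoints (between 1 and 10).
#' @return An integer matrix with `2^K` rows and `K` columns, with column
#'   names `y1..yK`.
#' @examples
#' config_matrix(2)
#' @export
config_matrix <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K != round(K))
    stop("`K` must be a single integer.", call. = FALSE)
  if (K < 1 || K > 10)
    stop("`K` must be between 1 and 10 (Q = 2^K response categories).",
         call. = FALSE)
  K <- as.integer(K)
  Q <- 2L^K
  # row q encodes the K-bit number Q - q (descending), most significant bit first
  H <- matrix(0L, Q, K)
  for (i in seq_len(Q)) {
    H[i, ] <- as.integer(bitwAnd(bitwShiftR(Q - i, (K - 1L):0L), 1L))
  }
  dimnames(H) <- list(NULL, paste0("y", seq_len(K)))
  H
}

#' Selection set of configurations with success on endpoint k
#'
#' The marginal success probability on endpoint `k` is the sum of the joint
#' response probabilities over the `2^(K-1)` configurations whose `k`-th
#' element is 1. This returns the indices of those rows of `H`, in `H` order.
#'
#' @param H Configuration matrix from [config_matrix()].
#' @param k Endpoint index (1-based).
#' @return Integer vector of row indices of `H`.
#' @export
selection_set <- function(H, k) {
  K <- ncol(H)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > K || k != round(k))
    stop("`k` must be an endpoint index in 1..", K, ".", call. = FALSE)
  which(H[, k] == 1L)
}

#' Encode joint binary responses as category indices
#'
#' Maps each row of an `n x K` binary outcome matrix to the index `q` of the
#' matching row of the configuration matrix `H`. The encoding is bijective:
#' `decode_categories()` inverts it exactly.
#'
#' @param Y An `n x K` matrix (or data frame) of 0/1 outcomes, columns ordered
#'   as the endpoints of `H`.
#' @param H Configuration matrix from [config_matrix()].
#' @return Integer vector of category indices in `1..Q`.
#' @export
encode_responses <- function(Y, H) {
  Y <- as.matrix(Y)
  K <- ncol(H)
  if (ncol(Y) != K)
    stop("`Y` must have ", K, " outcome columns to match `H`.", call. = FALSE)
  if (anyNA(Y) || !all(Y %in% c(0, 1)))
    stop("All outcome entries must be 0 or 1.", call. = FALSE)
  Q <- nrow(H)
  # H row q encodes bit value Q - q: invert that map directly
  bits <- Y %*% 2^((K - 1L):0L)
  as.integer(Q - bits)
}

#' @rdname encode_responses
#' @param cat Integer vector of category indices in `1..Q`.
#' @return `decode_categories()` returns the `n x K` binary outcome matrix.
#' @export
decode_categories <- function(cat, H) {
  if (any(cat < 1L | cat > nrow(H)))
    stop("Category indices must lie in 1..", nrow(H), ".", call. = FALSE)
  H[cat, , drop = FALSE]
}

#' Assemble a design matrix with role metadata
#'
#' Builds the `n x (P+1)` design matrix of the linear predictor: an intercept,
#' the binary treatment indicator, covariate columns, and treatment-covariate
#' (or covariate-covariate) interaction columns as elementwise products.
#' Column roles are retained so that counterfactual profiles (treatment forced
#' to 0 or 1, interactions recomputed) can be constructed downstream.
#'
#' Covariates are used on the scale supplied: no automatic standardization,
#' since subpopulations are defined by raw covariate values or intervals.
#'
#' @param data A data frame with one row per subject.
#' @param treatment Name of the 0/1 treatment indicator column.
#' @param covariates Character vector of covariate column names (possibly
#'   empty). Binary or continuous; factors are not expanded automatically.
#' @param interactions List of character pairs of column names whose product
#'   enters the predictor, e.g. `list(c("treat", "z"))`. The default `NULL`
#'   adds a treatment interaction for every covariate (the trial model with
#'   observable heterogeneity); use `list()` for no interactions.
#' @return An object of class `bmlr_design`: a list with the numeric matrix
#'   `X` (first column the intercept), `roles` (a tibble of column roles), and
#'   the column-name metadata needed for counterfactual construction.
#' @export
build_design <- function(data, treatment, covariates = character(),
                         interactions = NULL) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(treatment, covariates), names(data))
  if (length(missing_cols) > 0)
    stop("Column(s) not found in `data`: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tr <- data[[treatment]]
  if (anyNA(tr) || !all(tr %in% c(0, 1)))
    stop("Treatment column `", treatment, "` must be coded 0/1.", call. = FALSE)
  if (is.null(interactions))
    interactions <- lapply(covariates, function(v) c(treatment, v))
  stopifnot(is.list(interactions))

  n <- nrow(data)
  X <- matrix(1, n, 1)
  cols <- "(Intercept)"
  roles <- "intercept"
  X <- cbind(X, as.numeric(tr)); cols <- c(cols, treatment)
  roles <- c(roles, "treatment")
  for (v in covariates) {
    xv <- data[[v]]
    if (!is.numeric(xv))
      stop("Covariate `", v, "` must be numeric.", call. = FALSE)
    X <- cbind(X, xv); cols <- c(cols, v); roles <- c(roles, "covariate")
  }
  for (pr in interactions) {
    if (length(pr) != 2 || !all(pr %in% cols))
      stop("Each interaction must name two existing design columns.",
           call. = FALSE)
    X <- cbind(X, X[, match(pr[1], cols)] * X[, match(pr[2], cols)])
    cols <- c(cols, paste(pr, collapse = ":")); roles <- c(roles, "interaction")
  }
  colnames(X) <- cols
  if (!all(is.finite(X)))
    stop("Design matrix contains non-finite values.", call. = FALSE)
  structure(
    list(X = X,
         roles = tibble::tibble(column = cols, role = roles),
         treatment = treatment, covariates = covariates,
         interactions = interactions),
    class = "bmlr_design")
}

# Build a single counterfactual profile (with intercept) for covariate values
# `values` (named) and treatment arm `arm`, recomputing interactions.
profile_row <- function(design, values, arm) {
  cols <- design$roles$column
  x <- numeric(length(cols))
  names(x) <- cols
  x["(Intercept)"] <- 1
  x[design$treatment] <- arm
  for (v in design$covariates) {
    if (!v %in% names(values))
      stop("No value supplied for covariate `", v, "`.", call. = FALSE)
    x[v] <- values[[v]]
  }
  for (pr in design$interactions) {
    x[paste(pr, collapse = ":")] <- x[pr[1]] * x[pr[2]]
  }
  x
}

# Counterfactual design matrix for observed covariate rows `data` with the
# treatment column forced to `arm` and interactions recomputed.
profile_matrix <- function(design, data, arm) {
  data <- as.data.frame(data)
  cols <- design$roles$column
  n <- nrow(data)
  X <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  X[, "(Intercept)"] <- 1
  X[, design$treatment] <- arm
  for (v in design$covariates) X[, v] <- data[[v]]
  for (pr in design$interactions)
    X[, paste(pr, collapse = ":")] <- X[, pr[1]] * X[, pr[2]]
  X
}
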