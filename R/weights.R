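#' Pairwise-comparison judgment matrix
#'
#' Validates a Saaty-style reciprocal matrix: unit diagonal, a_ij = 1/a_ji,
#' order 2..15 (the random-index table stops at 15).
#'
#' @param m square numeric matrix of positive entries.
#' @param tol reciprocity tolerance.
#' @export
judgment_matrix <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (ncol(m) != n) stop("judgment matrix must be square", call. = FALSE)
  if (n < 2 || n > 15)
    stop("judgment matrix order must be between 2 and 15 (got ", n, ")",
         call. = FALSE)
  if (any(m <= 0)) stop("judgment matrix entries must be positive",
                        call. = FALSE)
  if (any(abs(diag(m) - 1) > tol))
    stop("judgment matrix diagonal must be 1", call. = FALSE)
  if (any(abs(m * t(m) - 1) > 1e-6))
    stop("judgment matrix is not reciprocal (a_ij != 1/a_ji)", call. = FALSE)
  structure(list(m = m, n = n), class = "judgment_matrix")
}

# Saaty's random consistency index, orders 1..15.
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
              1.51, 1.48, 1.56, 1.57, 1.59)

#' Weight vector container
#'
#' Nonnegative indicator weights summing to 1 (checked to 1e-9 unless
#' `normalize = TRUE` rescales first).
#'
#' @param weights named nonnegative numeric vector (names are indicator
#'   codes).
#' @param kind `"ahp"`, `"eem"` or `"combined"`.
#' @param epoch optional epoch label.
#' @param normalize rescale to sum 1 instead of erroring.
#' @export
weight_set <- function(weights, kind = c("ahp", "eem", "combined"),
                       epoch = NULL, normalize = FALSE) {
  kind <- match.arg(kind)
  if (is.null(names(weights)) || anyDuplicated(names(weights)))
    stop("weights must be uniquely named by indicator code", call. = FALSE)
  if (any(weights < -1e-12))
    stop("weights must be nonnegative", call. = FALSE)
  weights <- pmax(weights, 0)
  s <- sum(weights)
  if (normalize) {
    if (s <= 0) stop("cannot normalize an all-zero weight vector",
                     call. = FALSE)
    weights <- weights / s
  } else if (abs(s - 1) > 1e-9) {
    stop(kind, " weights sum to ", format(s), ", not 1", call. = FALSE)
  }
  structure(list(kind = kind, weights = weights, epoch = epoch),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<weight_set: %s%s>\n", x$kind,
              if (is.null(x$epoch)) "" else paste0(", epoch ", x$epoch)))
  print(round(x$weights, 4))
  invisible(x)
}

#' AHP weights and consistency report
#'
#' Principal-eigenvector weights of a reciprocal judgment matrix, computed by
#' power iteration (relative tolerance 1e-12). Consistency follows Saaty:
#' CI = (lambda_max - n)/(n - 1), CR = CI/RI(n), acceptable when CR < 0.1.
#' Orders 1-2 are always consistent (CR = 0).
#'
#' @param m a [judgment_matrix()] (or plain matrix, validated on the fly).
#' @param codes optional names for the weights (default w1..wn).
#' @return list with `weights` (a [weight_set()]) and `consistency` (fields
#'   `lambda_max`, `CI`, `CR`, `passes`).
#' @export
ahp_weights <- function(m, codes = NULL) {
  if (!inherits(m, "judgment_matrix")) m <- judgment_matrix(m)
  A <- m$m; n <- m$n
  v <- rep(1 / n, n)
  for (it in 1:10000) {
    v2 <- as.numeric(A %*% v)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v) / pmax(v, 1e-300)) < 1e-12) { v <- v2; break }
    v <- v2
  }
  lambda <- mean(as.numeric(A %*% v) / v)
  CI <- (lambda - n) / (n - 1)
  CR <- if (n <= 2) 0 else CI / saaty_ri[n]
  if (is.null(codes)) codes <- paste0("w", seq_len(n))
  list(
    weights = weight_set(stats::setNames(v, codes), kind = "ahp",
                         normalize = TRUE),
    consistency = list(lambda_max = lambda, CI = CI, CR = CR,
                       passes = CR < 0.1))
}

#' Entropy (information-entropy) weights from an indicator stack
#'
#' For each indicator j over the n valid cells, the cell share is
#' P_ij = s_ij / sum_i s_ij of the (polarity-standardized, nonnegative)
#' values, the entropy is E_j = -(1/ln n) * sum_i P_ij ln P_ij with
#' 0*ln 0 := 0, and the weight is W_j = (1 - E_j) / sum_j (1 - E_j). A
#' near-uniform indicator carries entropy ~1 and weight ~0.
#'
#' @param stack an [indicator_stack()]; all layers share a nodata mask.
#' @param standardize standardize each layer to [0,1] with its polarity first
#'   (the default, and the construction used throughout the pipeline). With
#'   `FALSE`, raw layer values are used and must be nonnegative.
#' @param minmax optional supplied min/max table passed to [standardize()].
#' @return a [weight_set()] of kind `"eem"`; entropies attached as
#'   `attr(, "entropy")`.
#' @export
entropy_weights <- function(stack, standardize = TRUE, minmax = NULL) {
  stopifnot(inherits(stack, "indicator_stack"))
  codes <- names(stack$layers)
  E <- stats::setNames(numeric(length(codes)), codes)
  for (code in codes) {
    layer <- stack$layers[[code]]
    s <- if (standardize) {
      standardize(layer, minmax = minmax_for(minmax, code))$values
    } else layer$grid$values
    s <- s[!is.na(s)]
    if (length(s) < 2)
      stop("indicator ", code, " has fewer than 2 valid cells", call. = FALSE)
    if (any(s < 0))
      stop("entropy weights need nonnegative values (indicator ", code, ")",
           call. = FALSE)
    tot <- sum(s)
    if (tot <= 0) {
      # all-zero standardized layer: every share is 0, entropy is 0 by the
      # term-wise 0*ln 0 convention
      E[code] <- 0
      next
    }
    p <- s / tot
    terms <- ifelse(p > 0, p * log(p), 0)
    E[code] <- -sum(terms) / log(length(s))
  }
  d <- 1 - E
  if (sum(d) <= 1e-12) {
    worst <- codes[which.max(E)]
    stop("all indicators are maximally entropic (constant layers, e.g. ",
         worst, "): entropy weights undefined", call. = FALSE)
  }
  w <- weight_set(d / sum(d), kind = "eem", epoch = stack$epoch)
  attr(w, "entropy") <- E
  w
}

#' Fuse subjective and objective weights
#'
#' Minimum-relative-information-entropy combination: the normalized geometric
#' mean W_j = sqrt(W_j^AHP * W_j^EEM) / sum_j sqrt(W_j^AHP * W_j^EEM).
#'
#' @param ahp [weight_set()] of kind `"ahp"`.
#' @param eem [weight_set()] of kind `"eem"` over the same codes.
#' @return a [weight_set()] of kind `"combined"`.
#' @export
combine_weights <- function(ahp, eem) {
  stopifnot(inherits(ahp, "weight_set"), inherits(eem, "weight_set"))
  if (!setequal(names(ahp$weights), names(eem$weights)))
    stop("AHP and entropy weight sets cover different indicator codes",
         call. = FALSE)
  codes <- names(ahp$weights)
  g <- sqrt(ahp$weights[codes] * eem$weights[codes])
  weight_set(g / sum(g), kind = "combined", epoch = eem$epoch,
             normalize = TRUE)
}
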