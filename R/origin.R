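#' Per-nucleus maternal/fetal allele totals
#'
#' Sums maternal-strain and fetal-strain reads over all SNPs for each
#' nucleus.  The maternal fraction is `NA` at zero coverage.
#'
#' @param allele An [allele_counts()] object.
#' @return data.frame with columns `barcode`, `m`, `f`, `coverage`,
#'   `fraction`.
#' @export
allele_fractions <- function(allele) {
  stopifnot(inherits(allele, "allele_counts"))
  m <- Matrix::colSums(allele$maternal)
  f <- Matrix::colSums(allele$fetal)
  cov <- m + f
  data.frame(barcode = colnames(allele$maternal),
             m = as.numeric(m), f = as.numeric(f),
             coverage = as.numeric(cov),
             fraction = ifelse(cov > 0, m / cov, NA_real_),
             stringsAsFactors = FALSE)
}

#' Classify nucleus origin from strain-allele counts
#'
#' Two-hypothesis Bayes classifier with uniform prior.  Under the
#' maternal hypothesis each read carries the maternal allele with
#' probability `1 - error`; under the fetal hypothesis with probability
#' `error` (both strains assumed homozygous at informative sites).  The
#' posterior probability of maternal origin is computed from the two
#' binomial likelihoods; a nucleus is called maternal when the posterior
#' reaches `tau`, fetal when it falls below `1 - tau`, and ambiguous
#' otherwise or when coverage is below `min_coverage`.
#'
#' @param m,f Maternal- and fetal-allele read totals (vectors).
#' @param error Per-read wrong-strain-allele probability in `[0, 0.5)`.
#' @param tau Posterior threshold (default 0.99).
#' @param min_coverage Minimum informative reads to make a call
#'   (default 5).
#' @return data.frame with `m`, `f`, `fraction`, `posterior_maternal`,
#'   `call`.
#' @export
classify_origin <- function(m, f, error = 0.01, tau = 0.99,
                            min_coverage = 5) {
  if (error < 0 || error >= 0.5) {
    stop("error must lie in [0, 0.5)", call. = FALSE)
  }
  stopifnot(length(m) == length(f), all(m >= 0), all(f >= 0))
  n <- m + f
  if (error == 0) {
    # degenerate likelihoods: any cross-strain read has probability 0
    post <- ifelse(n == 0 | (m > 0 & f > 0), 0.5,
                   ifelse(m > 0, 1, 0))
  } else {
    # log-likelihood ratio maternal vs fetal; binomial coefficients cancel
    llm <- stats::dbinom(m, n, 1 - error, log = TRUE)
    llf <- stats::dbinom(m, n, error, log = TRUE)
    post <- 1 / (1 + exp(llf - llm))
    post[n == 0] <- 0.5
  }
  call <- rep("ambiguous", length(m))
  call[post >= tau] <- "maternal"
  call[post <= 1 - tau] <- "fetal"
  call[n < min_coverage] <- "ambiguous"
  data.frame(m = m, f = f,
             fraction = ifelse(n > 0, m / n, NA_real_),
             posterior_maternal = post, call = call,
             stringsAsFactors = FALSE)
}

#' Classify origin for every nucleus of an allele-count object
#'
#' @param allele An [allele_counts()] object.
#' @inheritParams classify_origin
#' @return data.frame keyed by `barcode` with the [classify_origin()]
#'   columns.
#' @export
origin_calls <- function(allele, error = 0.01, tau = 0.99,
                         min_coverage = 5) {
  af <- allele_fractions(allele)
  cls <- classify_origin(af$m, af$f, error = error, tau = tau,
                         min_coverage = min_coverage)
  cbind(barcode = af$barcode, cls, stringsAsFactors = FALSE)
}

#' Maternal/fetal origin composition per annotated cluster
#'
#' @param labels Named character vector of cluster labels (names are
#'   barcodes).
#' @param calls data.frame from [origin_calls()] with `barcode` and
#'   `call`.
#' @return data.frame per cluster with counts and percentages of
#'   maternal, fetal and ambiguous calls (percentages sum to 100).
#' @export
cluster_origin_composition <- function(labels, calls) {
  if (!all(names(labels) %in% calls$barcode)) {
    stop("labels contain barcodes absent from origin calls", call. = FALSE)
  }
  call_by_bc <- stats::setNames(calls$call, calls$barcode)
  df <- data.frame(cluster = as.character(labels),
                   call = call_by_bc[names(labels)],
                   stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df, df$cluster), function(d) {
    n <- nrow(d)
    counts <- vapply(c("maternal", "fetal", "ambiguous"),
                     function(k) sum(d$call == k), numeric(1))
    data.frame(cluster = d$cluster[1], n = n,
               n_maternal = counts[1], n_fetal = counts[2],
               n_ambiguous = counts[3],
               pct_maternal = 100 * counts[1] / n,
               pct_fetal = 100 * counts[2] / n,
               pct_ambiguous = 100 * counts[3] / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
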