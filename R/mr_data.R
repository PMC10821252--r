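#' Individual-level Mendelian-randomization dataset
#'
#' Bundles a genotype matrix of minor-allele counts, a continuous exposure
#' (possibly with missing entries) and a binary outcome into the unit of
#' analysis used throughout the package. Most users will build one from a
#' tibble with [mr_data()] or simulate one with [simulate_pool()].
#'
#' @param data A data frame with one row per individual, containing the
#'   outcome column, the exposure column (`NA` = missing) and one column per
#'   genetic instrument.
#' @param outcome Name of the binary outcome column (values 0/1).
#' @param exposure Name of the continuous exposure column.
#' @param instruments Character vector of instrument column names. Defaults to
#'   every column matching `^Z[0-9]+$`.
#' @param validate_genotypes If `TRUE` (default for raw data), instrument
#'   columns must contain only minor-allele counts 0, 1, 2. Set to `FALSE`
#'   for already-standardized (real-valued) instruments.
#'
#' @return An object of class `mr_data`: a list with elements
#'   `genotypes` (n x J numeric matrix), `exposure` (length-n numeric, `NA`
#'   for missing), `outcome` (length-n integer 0/1), `standardized` (logical),
#'   and `scaling` (centers/scales applied by [mr_standardize()]).
#'
#' @examples
#' d <- tibble::tibble(Y = c(0, 1, 1, 0), X = c(0.1, NA, -0.3, 1.2),
#'                     Z1 = c(0, 1, 2, 1), Z2 = c(1, 1, 0, 2))
#' mr_data(d)
#' @export
mr_data <- function(data, outcome = "Y", exposure = "X",
                    instruments = grep("^Z[0-9]+$", names(data), value = TRUE),
                    validate_genotypes = TRUE) {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) stop("outcome column '", outcome, "' not found")
  if (!exposure %in% names(data)) stop("exposure column '", exposure, "' not found")
  if (length(instruments) < 1L) stop("no instrument columns found")
  y <- data[[outcome]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome entries must be exactly 0 or 1")
  }
  z <- as.matrix(data[instruments])
  storage.mode(z) <- "double"
  if (validate_genotypes) {
    bad <- which(!(z %in% c(0, 1, 2)), arr.ind = FALSE)
    if (length(bad)) {
      ij <- arrayInd(bad[1L], dim(z))
      stop(sprintf("genotype value %s at row %d, column %s is not in {0,1,2}",
                   format(z[bad[1L]]), ij[1L], instruments[ij[2L]]))
    }
  }
  x <- as.numeric(data[[exposure]])
  if (length(x) != nrow(z) || length(y) != nrow(z)) {
    stop("outcome, exposure and genotypes must have equal length")
  }
  new_mr_data(genotypes = z, exposure = x, outcome = as.integer(y),
              standardized = FALSE)
}

new_mr_data <- function(genotypes, exposure, outcome, standardized = FALSE,
                        scaling = NULL, oracle_exposure = NULL, truth = NULL) {
  colnames(genotypes) <- colnames(genotypes) %||% paste0("Z", seq_len(ncol(genotypes)))
  structure(
    list(genotypes = genotypes, exposure = exposure, outcome = outcome,
         standardized = standardized, scaling = scaling,
         oracle_exposure = oracle_exposure, truth = truth),
    class = "mr_data"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mr_data <- function(x, ...) {
  cat(sprintf(
    "<mr_data> %d individuals, %d instruments; exposure observed for %d (missing %d)%s\n",
    n_total(x), n_instruments(x), n_complete(x), n_missing(x),
    if (isTRUE(x$standardized)) "; standardized" else ""))
  invisible(x)
}

#' Sample-size accessors for `mr_data`
#'
#' `n_complete()` counts individuals with an observed exposure (dataset A in a
#' one-sample-with-missing-exposure design), `n_missing()` those with the
#' exposure missing (dataset B), `n_total()` their sum and `n_instruments()`
#' the number of genetic instruments.
#'
#' @param x An `mr_data` object.
#' @return An integer count.
#' @export
n_complete <- function(x) sum(!is.na(x$exposure))

#' @rdname n_complete
#' @export
n_missing <- function(x) sum(is.na(x$exposure))

#' @rdname n_complete
#' @export
n_total <- function(x) length(x$outcome)

#' @rdname n_complete
#' @export
n_instruments <- function(x) ncol(x$genotypes)

#' Missingness mask of the exposure
#'
#' @param x An `mr_data` object.
#' @return A logical vector, `TRUE` where the exposure is missing.
#' @export
exposure_missing_mask <- function(x) is.na(x$exposure)

#' @importFrom tibble as_tibble
#' @method as_tibble mr_data
#' @export
as_tibble.mr_data <- function(x, ...) {
  tibble::as_tibble(cbind(
    data.frame(id = seq_len(n_total(x)), Y = x$outcome, X = x$exposure),
    as.data.frame(x$genotypes)
  ))
}

#' @export
as.data.frame.mr_data <- function(x, ...) as.data.frame(as_tibble(x))

validate_mr_data <- function(x) {
  stopifnot(inherits(x, "mr_data"))
  n <- length(x$outcome)
  if (nrow(x$genotypes) != n || length(x$exposure) != n) {
    stop("genotypes, exposure and outcome must have equal first-dimension length")
  }
  if (!all(x$outcome %in% c(0L, 1L))) stop("outcome entries must be exactly 0 or 1")
  invisible(x)
}

#' Standardize instruments and exposure
#'
#' Rescales each genotype column and the *observed* entries of the exposure to
#' sample mean 0 and standard deviation 1, as the model assumes. Missing
#' exposure entries are left missing; the outcome is untouched. The centers
#' and scales used are stored in the returned object's `scaling` field so that
#' effect estimates remain interpretable on the original measurement scale.
#' Only the observed exposure values enter the exposure mean/SD.
#'
#' @param x An `mr_data` object.
#' @return A standardized `mr_data` object.
#' @examples
#' d <- tibble::tibble(Y = c(0, 1, 1, 0), X = c(1, 4, NA, 2),
#'                     Z1 = c(0, 1, 2, 1))
#' mr_standardize(mr_data(d))
#' @export
mr_standardize <- function(x) {
  validate_mr_data(x)
  z <- x$genotypes
  mu <- colMeans(z)
  sdv <- apply(z, 2L, stats::sd)
  zero <- which(sdv == 0 | !is.finite(sdv))
  if (length(zero)) {
    stop("monomorphic instrument (zero variance): column ",
         paste(colnames(z)[zero], collapse = ", "))
  }
  z <- sweep(sweep(z, 2L, mu), 2L, sdv, "/")
  obs <- !is.na(x$exposure)
  if (sum(obs) >= 2L) {
    xm <- mean(x$exposure[obs]); xs <- stats::sd(x$exposure[obs])
    if (xs == 0) stop("observed exposure has zero variance")
  } else {
    xm <- 0; xs <- 1  # nothing to standardize on
  }
  xe <- (x$exposure - xm) / xs
  scaling <- list(
    genotype_center = mu, genotype_scale = sdv,
    exposure_center = xm, exposure_scale = xs
  )
  out <- x
  out$genotypes <- z
  out$exposure <- xe
  out$standardized <- TRUE
  out$scaling <- scaling
  out
}
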