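#' Standardize a numeric vector
#'
#' Subtracts the sample mean and divides by the sample SD (n - 1
#' denominator). `NA`s are ignored when computing the mean and SD and
#' preserved in the output.
#'
#' @param x Numeric vector with positive SD.
#' @return Vector of the same length with mean 0 and SD 1.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(x) {
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) {
    stop("cannot standardize: SD of x is zero or undefined", call. = FALSE)
  }
  (x - mean(x, na.rm = TRUE)) / s
}

#' Read a table of repeated phenotype measurements
#'
#' Reads a delimited file (comma- or tab-separated, sniffed from the header
#' line unless `sep` is given) with a header row, as produced by most
#' phenotype databases: one row per subject, one column per repeated
#' measurement of the same trait.
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field separator; `NULL` (default) sniffs `,` vs tab.
#' @return A data frame.
#' @export
read_repeated_measurements <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE)
}

# resolve a pair of measurement columns; default: the first two numeric ones
.pick_columns <- function(data, columns) {
  if (is.null(columns)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    if (length(num) < 2) {
      stop("need at least two numeric measurement columns", call. = FALSE)
    }
    columns <- num[1:2]
  }
  if (length(columns) != 2 || !all(columns %in% names(data))) {
    stop("columns must name two columns of the data; got: ",
         paste(columns, collapse = ", "), call. = FALSE)
  }
  columns
}

#' Estimate phenotype measurement error from repeated measurements
#'
#' Given two measurements of the same trait on each subject, estimates the
#' measurement-error SD and agreement statistics on the standardized scale.
#' Incomplete pairs are dropped (pairwise deletion) with a message.
#'
#' Writing each observed measurement as true trait plus independent error
#' of equal variance, the difference of the two standardized columns has
#' variance \eqn{2\sigma_e^2/(1+\sigma_e^2)}; half the difference variance
#' therefore estimates the *attenuated* error variance
#' \eqn{\sigma_e^2/(1+\sigma_e^2)} (error in observed-SD units), and
#' de-attenuating gives `sigma_e_moment`, the error SD in units of the true
#' (error-free) phenotype SD — the unit the power calculations expect. The
#' same model implies a between-column correlation of
#' \eqn{1/(1+\sigma_e^2)}, so `sigma_e_moment` equals
#' \eqn{\sqrt{(1-r)/r}} at the sample correlation `r`.
#'
#' `mad_standardized`, the mean absolute difference between the
#' standardized columns, is reported as the operational headline summary of
#' measurement disagreement; it differs from `sigma_e_moment` by a
#' distribution-dependent constant and is not plugged into power formulas.
#'
#' @param data A data frame of repeated measurements (see
#'   [read_repeated_measurements()]).
#' @param columns Character vector naming the two measurement columns;
#'   default: the first two numeric columns.
#' @return An object of class `measurement_error_estimate`: a list with
#'   `n_pairs`, `n_dropped`, `mad_standardized`, `sigma_e_attenuated`,
#'   `sigma_e_moment`, `pearson_r`, and `bland_altman` (bias and 95% limits
#'   of agreement).
#' @examples
#' set.seed(1)
#' z <- rnorm(500)
#' d <- data.frame(m1 = z + rnorm(500, 0, 0.3), m2 = z + rnorm(500, 0, 0.3))
#' estimate_error(d)
#' @export
estimate_error <- function(data, columns = NULL) {
  columns <- .pick_columns(data, columns)
  x <- data[[columns[1]]]
  y <- data[[columns[2]]]
  keep <- complete.cases(x, y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " incomplete pair(s)")
  }
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) {
    stop("need at least 2 complete measurement pairs", call. = FALSE)
  }
  s1 <- standardize(x)
  s2 <- standardize(y)
  d <- s1 - s2
  att2 <- var(d) / 2  # estimates sigma_e^2 / (1 + sigma_e^2)
  sigma_e <- if (att2 >= 1) {
    warning("difference variance implies no true-trait signal; ",
            "sigma_e_moment is infinite", call. = FALSE)
    Inf
  } else {
    sqrt(att2 / (1 - att2))
  }
  ba <- bland_altman(data.frame(a = x, b = y), columns = c("a", "b"))
  structure(
    list(columns = columns,
         n_pairs = length(x),
         n_dropped = n_dropped,
         mad_standardized = mean(abs(d)),
         sigma_e_attenuated = sqrt(att2),
         sigma_e_moment = sigma_e,
         pearson_r = cor(s1, s2),
         bland_altman = ba[c("bias", "lower", "upper")]),
    class = "measurement_error_estimate")
}

#' @export
print.measurement_error_estimate <- function(x, ...) {
  cat("Measurement-error estimate from", x$n_pairs, "repeated pairs",
      sprintf("(%d dropped)\n", x$n_dropped))
  cat(sprintf("  mean |standardized difference|: %.4f\n",
              x$mad_standardized))
  cat(sprintf("  sigma_e (true-phenotype SD units): %.4f", x$sigma_e_moment))
  cat(sprintf("   [attenuated, observed units: %.4f]\n",
              x$sigma_e_attenuated))
  cat(sprintf("  Pearson r between columns: %.4f\n", x$pearson_r))
  cat(sprintf("  Bland-Altman bias %.4f, 95%% limits (%.4f, %.4f)\n",
              x$bland_altman$bias, x$bland_altman$lower,
              x$bland_altman$upper))
  invisible(x)
}

#' Bland-Altman agreement between two standardized measurements
#'
#' Differences and averages of the standardized measurement columns, the
#' bias (mean difference) and the 95% limits of agreement
#' (bias +/- 1.96 SD of the differences).
#'
#' @inheritParams estimate_error
#' @return A list with `bias`, `lower`, `upper`, and the paired `average`
#'   and `difference` vectors for plotting.
#' @export
bland_altman <- function(data, columns = NULL) {
  columns <- .pick_columns(data, columns)
  x <- data[[columns[1]]]
  y <- data[[columns[2]]]
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) {
    stop("need at least 2 complete measurement pairs", call. = FALSE)
  }
  s1 <- standardize(x)
  s2 <- standardize(y)
  d <- s1 - s2
  bias <- mean(d)
  sdd <- sd(d)
  list(bias = bias,
       lower = bias - 1.96 * sdd,
       upper = bias + 1.96 * sdd,
       average = (s1 + s2) / 2,
       difference = d)
}
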