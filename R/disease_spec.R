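#' Disease specification for the liability threshold model
#'
#' Bundles the scalar parameters of a polygenic disease under the liability
#' threshold model: the lifetime morbid risk `f` (probability that an
#' individual develops the disease at some point in life), the heritability
#' of liability `h2`, an optional shared-environment variance fraction `c2`,
#' and the proportion `pi` of the additive genetic variance captured by known
#' SNP associations.  Total liability has unit variance; disease occurs when
#' liability reaches the threshold `T = qnorm(1 - f)`.
#'
#' @param f Lifetime morbid risk, in (0, 1).
#' @param h2 Heritability of liability, in \[0, 1\].
#' @param c2 Shared-environment variance fraction, in \[0, 1); all members of
#'   a family share a single common environmental component with this
#'   variance.  Default 0.
#' @param pi Proportion of heritability explained by measured SNPs, in
#'   \[0, 1\].  The measured genetic component of liability then has variance
#'   `v = pi * h2`.  Default 0.
#'
#' @return An object of class `disease_spec`: a list with elements `f`, `h2`,
#'   `c2`, `pi`, the derived liability threshold `threshold`, and the
#'   measured-component variance `v`.
#'
#' @examples
#' crohn <- disease_spec(f = 0.005, h2 = 0.56, pi = 0.135)
#' crohn$threshold  # about 2.576
#' @export
disease_spec <- function(f, h2, c2 = 0, pi = 0) {
  stopifnot(is.numeric(f), length(f) == 1L,
            is.numeric(h2), length(h2) == 1L,
            is.numeric(c2), length(c2) == 1L,
            is.numeric(pi), length(pi) == 1L)
  f <- unname(f); h2 <- unname(h2); c2 <- unname(c2); pi <- unname(pi)
  if (!(f > 0 && f < 1))
    stop("lifetime morbid risk `f` must lie strictly in (0, 1), got ", f)
  if (h2 < 0 || h2 > 1)
    stop("heritability `h2` must lie in [0, 1], got ", h2)
  if (c2 < 0 || c2 >= 1)
    stop("shared-environment fraction `c2` must lie in [0, 1), got ", c2)
  if (pi < 0 || pi > 1)
    stop("proportion explained `pi` must lie in [0, 1], got ", pi)
  if (h2 + c2 > 1)
    stop("h2 + c2 must not exceed 1 (total liability variance is 1)")
  structure(
    list(f = f, h2 = h2, c2 = c2, pi = pi,
         threshold = liability_threshold(f), v = pi * h2),
    class = "disease_spec"
  )
}

#' Liability threshold for a given disease frequency
#'
#' Under the liability threshold model an individual develops the disease
#' exactly when the (unit-variance, zero-mean) liability is at least
#' `T = qnorm(1 - f)`.
#'
#' @param f Lifetime morbid risk, in (0, 1).
#' @return The threshold on the standard-normal liability scale.
#' @examples
#' liability_threshold(0.5)    # 0
#' liability_threshold(0.005)  # 2.5758...
#' @export
liability_threshold <- function(f) {
  if (!is.numeric(f) || any(f <= 0) || any(f >= 1))
    stop("`f` must lie strictly in (0, 1)")
  stats::qnorm(1 - f)
}

#' @export
print.disease_spec <- function(x, ...) {
  cat("Disease specification (liability threshold model)\n")
  cat(sprintf("  lifetime risk f  : %g\n", x$f))
  cat(sprintf("  heritability h2  : %g\n", x$h2))
  if (x$c2 > 0) cat(sprintf("  shared env c2    : %g\n", x$c2))
  if (x$pi > 0) cat(sprintf("  pi explained     : %g  (v = %g)\n", x$pi, x$v))
  cat(sprintf("  threshold T      : %.6f\n", x$threshold))
  invisible(x)
}

#' Read a disease specification from a YAML or JSON config file
#'
#' Accepts a flat mapping with keys `f`, `h2` and optionally `c2`, `pi`.
#' JSON is parsed with \pkg{jsonlite} when available; a minimal
#' `key: value` YAML subset is parsed directly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [disease_spec()].
#' @export
read_disease_spec <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package")
    vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    keep <- grepl("^\\s*[A-Za-z0-9_]+\\s*:", txt)
    kv <- strsplit(sub("^\\s*", "", txt[keep]), "\\s*:\\s*")
    vals <- lapply(kv, function(p) as.numeric(p[2]))
    names(vals) <- vapply(kv, `[`, "", 1L)
  }
  disease_spec(f = vals$f, h2 = vals$h2,
               c2 = if (is.null(vals$c2)) 0 else vals$c2,
               pi = if (is.null(vals$pi)) 0 else vals$pi)
}
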