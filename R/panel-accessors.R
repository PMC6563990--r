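# Accessors for HmcPanel; slots are never touched directly by user code.

#' @rdname HmcPanel-class
#' @param x an \code{HmcPanel}.
#' @return \code{methylBS}, \code{unmethBS}, \code{methOxBS},
#'   \code{unmethOxBS}: the respective intensity matrices; \code{panelMask}:
#'   the logical mask (\code{TRUE} = invalid); \code{tissueLabel}: the tissue
#'   label.
#' @export
methylBS <- function(x) assay(x, "M_bs")

#' @rdname HmcPanel-class
#' @export
unmethBS <- function(x) assay(x, "U_bs")

#' @rdname HmcPanel-class
#' @export
methOxBS <- function(x) assay(x, "M_oxbs")

#' @rdname HmcPanel-class
#' @export
unmethOxBS <- function(x) assay(x, "U_oxbs")

#' @rdname HmcPanel-class
#' @export
panelMask <- function(x) assay(x, "mask")

#' @rdname HmcPanel-class
#' @export
tissueLabel <- function(x) metadata(x)$tissue

#' Published reference expectations for the three screening measures
#'
#' Loads the reference expected-similarity and expected-relative-accuracy
#' values reported for a 38-pair colorectal (matched healthy/cancer) BS/oxBS
#' cohort, shipped as plain TSV under \code{inst/extdata}. These are inputs
#' for the exact identity checks \eqn{E[SH] = 2E[S] - 1} and
#' \eqn{FDR_r(x_1|x_2) = 1 - SE_r(x_2|x_1)}; the package does not recompute
#' them (the underlying cohort data are external).
#'
#' @return list with \code{similarity} (data.frame: pair, tissue, E_S, E_SH)
#'   and, per tissue, 3x3 matrices \code{sensitivity} and \code{fdr}
#'   (conditioned measure in rows, conditioning measure in columns).
#' @export
referenceExpectations <- function() {
  f <- function(name) system.file("extdata", name, package = "hmcScreen",
                                  mustWork = TRUE)
  sim <- utils::read.delim(f("reference_expected_similarity.tsv"))
  sens <- utils::read.delim(f("reference_expected_sensitivity.tsv"))
  fdr <- utils::read.delim(f("reference_expected_fdr.tsv"))
  toMat <- function(df, col) {
    meas <- c("delta_m_inf", "delta_beta100", "delta_h")
    out <- list()
    for (tis in unique(df$tissue)) {
      d <- df[df$tissue == tis, ]
      m <- matrix(NA_real_, 3, 3, dimnames = list(meas, meas))
      m[cbind(match(d$x1, meas), match(d$x2, meas))] <- d[[col]]
      out[[tis]] <- m
    }
    out
  }
  list(similarity = sim,
       sensitivity = toMat(sens, "E_SE_r"),
       fdr = toMat(fdr, "E_FDR_r"))
}
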