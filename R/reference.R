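#' Published reference values for the automatic 3D MAPSE method
#'
#' Small tables of values printed in the clinical validation study of
#' continuous automatic 3D MAPSE monitoring in 50 postoperative cardiac
#' surgery patients, bundled for internal-consistency checks (the patient
#' data themselves are not shareable):
#' \describe{
#'   \item{agreement}{printed Bland-Altman bias and limits of agreement
#'     for the overall comparison, per-wall sub-groups, the analysis
#'     excluding the anterolateral wall, the mitral-surgery sub-group, and
#'     the interobserver comparison of the manual method.}
#'   \item{feasibility}{printed feasibility counts (numerator, denominator
#'     and the percentage as printed).}
#'   \item{lsc}{printed least-significant-change values by number of
#'     averaged measurements, for the automatic method overall, its
#'     mitral-surgery sub-group, and the manual reference method.}
#' }
#'
#' @param table one of `"agreement"`, `"feasibility"`, `"lsc"`.
#' @return data.frame.
#' @examples
#' reference_values("lsc")
#' @export
reference_values <- function(table = c("agreement", "feasibility", "lsc")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("reference_", table, ".csv"),
                      package = "mapse3d", mustWork = TRUE)
  read.csv(path)
}
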