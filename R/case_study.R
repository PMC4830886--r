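#' Six-triazole case-study data
#'
#' Published summary measurements for six antifungal triazole development
#' compounds plus the transport reference (antipyrine) and integrity
#' control (amoxicillin): per-compound Papp coefficients and relative Papp
#' from the BeWo placental-barrier model, differentiation BMC50 values
#' (with the transfer-corrected values as reported), and the in vivo
#' developmental-toxicity ordering from the corresponding rat prenatal
#' studies. These are report-precision values (Papp to 0.1 x 1e-6 cm/s,
#' relative Papp to 2 decimals, BMC to 0.1 uM); the underlying raw well
#' counts and chromatograms are not available.
#'
#' @return List with `papp` (data.frame), `bmc` (data.frame), and
#'   `in_vivo_order` (character, most toxic first).
#' @examples
#' cs <- triazole_case_study()
#' cs$papp
#' @export
triazole_case_study <- function() {
  ext <- function(f) system.file("extdata", f, package = "devtoxrank",
                                 mustWork = TRUE)
  papp <- utils::read.csv(ext("triazole_papp.csv"),
                          colClasses = c(compound = "character"))
  bmc <- utils::read.csv(ext("triazole_bmc.csv"),
                         colClasses = c(compound = "character"))
  list(papp = papp, bmc = bmc,
       in_vivo_order = read_ranking_file(ext("invivo_ranking.txt")))
}
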