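#' Bundled illustrative motif panel
#'
#' Loads the four-PWM panel shipped with the package (E2F, DREF, FOXJ2, RAM
#' — an E2F-family site, the DNA replication-related element, a
#' Forkhead-family site, and a novel corepressor-associated motif). These
#' matrices are synthetic reconstructions built for testing and simulation:
#' they carry the field's motif names and approximate consensus sequences but
#' are NOT measured matrices from any study (the file is named
#' `synthetic_motifs.meme` for that reason).
#'
#' @param background Optional length-4 background overriding the uniform one
#'   stored in the file.
#' @return Named list of [build_pwm()] objects.
#' @export
synthetic_motifs <- function(background = NULL) {
  path <- system.file("extdata", "synthetic_motifs.meme",
                      package = "regulonscan", mustWork = TRUE)
  read_pwms_meme(path, background = background)
}
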