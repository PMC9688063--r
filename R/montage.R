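#' Construct a Montage
#'
#' @param channels character vector of electrode labels.
#' @param positions numeric matrix (channels x 2) of head-circle
#'   coordinates (x to the right, y to the front), inside the unit circle.
#' @return A [Montage-class] object.
#' @export
montage <- function(channels, positions) {
  positions <- as.matrix(positions)
  rownames(positions) <- channels
  colnames(positions) <- c("x", "y")
  new("Montage", channels = as.character(channels), positions = positions)
}

#' The 19-channel international 10/20 montage
#'
#' The reference montage: 19 electrodes of the international 10/20 system
#' with schematic head-circle coordinates (nose up, x to the right).
#'
#' @return A [Montage-class] with channels Fp1, Fp2, F7, F3, Fz, F4, F8,
#'   T3, C3, Cz, C4, T4, T5, P3, Pz, P4, T6, O1, O2.
#' @examples
#' standardMontage1020()
#' @export
standardMontage1020 <- function() {
  ch <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
          "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  pos <- rbind(
    c(-0.309, 0.951), c(0.309, 0.951), c(-0.809, 0.5878), c(-0.55, 0.48),
    c(0, 0.5), c(0.55, 0.48), c(0.809, 0.5878), c(-1, 0), c(-0.5, 0),
    c(0, 0), c(0.5, 0), c(1, 0), c(-0.809, -0.5878), c(-0.55, -0.48),
    c(0, -0.5), c(0.55, -0.48), c(0.809, -0.5878), c(-0.309, -0.951),
    c(0.309, -0.951))
  montage(ch, pos)
}
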