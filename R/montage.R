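#' Simulated EEG montage
#'
#' A reduced 27-channel subset of an extended 10-20 montage covering the
#' sensorimotor strip, surrounding frontal/parietal rows and the occipital
#' area. Each channel carries approximate 2-D scalp coordinates (head-radius
#' units; x positive to the right, y positive to the front) used by the
#' Gaussian spatial mixing kernels of the generator.
#'
#' @return data.frame with columns `channel`, `x`, `y`
#' @export
#' @examples
#' head(default_montage())
default_montage <- function() {
  data.frame(
    channel = c("F3", "Fz", "F4",
                "FC3", "FCz", "FC4",
                "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
                "CP3", "CPz", "CP4",
                "P3", "Pz", "P4",
                "PO3", "POz", "PO4",
                "O1", "Oz", "O2"),
    x = c(-0.35, 0, 0.35,
          -0.38, 0, 0.38,
          -0.95, -0.75, -0.45, -0.22, 0, 0.22, 0.45, 0.75, 0.95,
          -0.38, 0, 0.38,
          -0.35, 0, 0.35,
          -0.28, 0, 0.28,
          -0.2, 0, 0.2),
    y = c(0.55, 0.6, 0.55,
          0.28, 0.3, 0.28,
          0, 0, 0, 0, 0, 0, 0, 0, 0,
          -0.28, -0.3, -0.28,
          -0.55, -0.6, -0.55,
          -0.75, -0.78, -0.75,
          -0.92, -0.95, -0.92),
    stringsAsFactors = FALSE
  )
}

#' Laplacian neighbour table
#'
#' Declared four-neighbour sets for every channel that can serve as a small
#' Laplacian centre in the simulated montage. Each centre is paired with four
#' approximately equidistant surrounding channels whose mean is subtracted
#' from it.
#'
#' @return named list: centre channel -> character vector of 4 neighbours
#' @export
laplacian_neighbours <- function() {
  list(
    C5  = c("T7", "C3", "FC3", "CP3"),
    C3  = c("C5", "C1", "FC3", "CP3"),
    C1  = c("C3", "Cz", "FCz", "CPz"),
    FC3 = c("F3", "C3", "FCz", "C5"),
    CP3 = c("C3", "P3", "CPz", "C5"),
    FCz = c("Fz", "Cz", "FC3", "FC4"),
    Cz  = c("C1", "C2", "FCz", "CPz"),
    CPz = c("Cz", "Pz", "CP3", "CP4"),
    C2  = c("C4", "Cz", "FCz", "CPz"),
    C4  = c("C2", "C6", "FC4", "CP4"),
    C6  = c("T8", "C4", "FC4", "CP4"),
    FC4 = c("F4", "C4", "FCz", "C6"),
    CP4 = c("C4", "P4", "CPz", "C6")
  )
}

#' Hemispheric region of each Laplacian candidate
#'
#' @return named character vector mapping candidate centres to
#'   `"left"`, `"center"` or `"right"`
#' @export
laplacian_regions <- function() {
  c(C5 = "left", C3 = "left", C1 = "left", FC3 = "left", CP3 = "left",
    FCz = "center", Cz = "center", CPz = "center",
    C2 = "right", C4 = "right", C6 = "right", FC4 = "right", CP4 = "right")
}

# Declared channel subsets for the two CSP stages. The study used 24- and
# 47-channel motor-centric subsets of a 64-channel cap; on the reduced
# simulated montage the first stage excludes the occipital row and the second
# uses every channel.
csp_channels_stage1 <- function() {
  setdiff(default_montage()$channel, c("O1", "Oz", "O2"))
}

csp_channels_stage2 <- function() {
  default_montage()$channel
}

# Nine monopolar channels feeding the two resting-state Laplacians:
# C3 and C4 with four neighbours each, sharing Cz on the central row.
predictor_laplacians <- function() {
  list(
    lap_C3 = list(center = "C3", neighbours = c("C5", "Cz", "FC3", "CP3")),
    lap_C4 = list(center = "C4", neighbours = c("C6", "Cz", "FC4", "CP4"))
  )
}
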