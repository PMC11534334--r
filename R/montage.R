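#' The 19-channel 10-10 scalp montage
#'
#' Channel labels and approximate 2-D head-plane coordinates for the
#' 19-electrode montage used throughout the package (Fp1/Fp2, F7/F3/Fz/F4/F8,
#' T7/C3/Cz/C4/T8, P7/P3/Pz/P4/P8, O1/O2).
#'
#' @return data.frame with columns `label`, `x`, `y` (unit head radius).
#' @export
montage_1010 <- function() {
  data.frame(
    label = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "T7", "C3", "Cz", "C4", "T8",
              "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
    x = c(-0.31, 0.31, -0.81, -0.55, 0, 0.55, 0.81,
          -1.00, -0.50, 0, 0.50, 1.00,
          -0.81, -0.55, 0, 0.55, 0.81, -0.31, 0.31),
    y = c(0.95, 0.95, 0.59, 0.49, 0.50, 0.49, 0.59,
          0.00, 0.00, 0.00, 0.00, 0.00,
          -0.59, -0.49, -0.50, -0.49, -0.59, -0.95, -0.95),
    stringsAsFactors = FALSE
  )
}

#' Channel neighbourhood of the 19-channel montage
#'
#' Template Delaunay-style neighbour relation used for spatial clustering in
#' the permutation tests. Symmetric and irreflexive; every channel has at
#' least one neighbour.
#'
#' @return named list: for each channel label, a character vector of its
#'   neighbouring channel labels.
#' @export
montage_neighbors <- function() {
  nb <- list(
    Fp1 = c("Fp2", "F7", "F3", "Fz"),
    Fp2 = c("Fp1", "F8", "F4", "Fz"),
    F7  = c("Fp1", "F3", "T7"),
    F3  = c("Fp1", "F7", "Fz", "C3"),
    Fz  = c("Fp1", "Fp2", "F3", "F4", "Cz"),
    F4  = c("Fp2", "F8", "Fz", "C4"),
    F8  = c("Fp2", "F4", "T8"),
    T7  = c("F7", "C3", "P7"),
    C3  = c("F3", "T7", "Cz", "P3"),
    Cz  = c("Fz", "C3", "C4", "Pz"),
    C4  = c("F4", "T8", "Cz", "P4"),
    T8  = c("F8", "C4", "P8"),
    P7  = c("T7", "P3", "O1"),
    P3  = c("C3", "P7", "Pz", "O1"),
    Pz  = c("Cz", "P3", "P4", "O1", "O2"),
    P4  = c("C4", "P8", "Pz", "O2"),
    P8  = c("T8", "P4", "O2"),
    O1  = c("P7", "P3", "Pz", "O2"),
    O2  = c("P8", "P4", "Pz", "O1")
  )
  # enforce symmetry
  for (ch in names(nb)) {
    for (other in nb[[ch]]) {
      if (!(ch %in% nb[[other]])) nb[[other]] <- c(nb[[other]], ch)
    }
  }
  nb
}

#' Build a channel adjacency matrix from a neighbour list
#'
#' @param channels character vector of channel labels in data order.
#' @param neighbors named neighbour list as from [montage_neighbors()];
#'   channels absent from the list get no neighbours.
#' @return logical `length(channels)` square matrix, symmetric, FALSE diagonal.
#' @export
channel_adjacency <- function(channels, neighbors = montage_neighbors()) {
  k <- length(channels)
  adj <- matrix(FALSE, k, k, dimnames = list(channels, channels))
  for (i in seq_len(k)) {
    nbi <- neighbors[[channels[i]]]
    if (is.null(nbi)) next
    adj[i, channels %in% nbi] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  adj
}
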