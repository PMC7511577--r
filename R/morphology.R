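#' Default geometry of the reduced pyramidal-neuron morphology
#'
#' The morphology is a 22-compartment reduction of a large (layer-five-like)
#' pyramidal neuron: a soma, a 13-compartment apical shaft
#' (`apdend1`..`apdend13`, 75 um each, spanning 0--975 um from the soma along
#' the soma-apical axis), a 3-compartment apical tuft spanning 975--1200 um,
#' a 3-compartment basal dendrite chain, and a 2-compartment axon stub.
#' Apical shaft diameter tapers linearly from `apical$diam_base` at the soma
#' end to `apical$diam_tip` at the tuft end.  All dimensions are in
#' micrometres and live in this one configuration block so the geometry can
#' be recalibrated without touching code.
#'
#' The default soma/apical diameters were calibrated jointly with
#' [passive_defaults()] against the six model input resistances (see the
#' methods vignette); everything else is a fixed structural default.
#'
#' @return A nested list of geometry parameters.
#' @export
geometry_defaults <- function() {
  list(
    soma   = list(length = 30, diam = 13.6918),
    apical = list(n = 13, length = 75, diam_base = 7.52658,
                  diam_tip = 2.89731),
    tuft   = list(n = 3, length = 75, diam = 2.76446),
    basal  = list(n = 3, length = 120, diam = c(4, 3, 2)),
    axon   = list(n = 2, length = 50, diam = c(2, 1.5))
  )
}

#' Default level assignment for every compartment
#'
#' Maps each compartment id to its row ("level") of the conductance density
#' table: levels 0--1 the two axonal compartments, level 2 the soma, levels
#' 3--5 the basal chain, levels 6--18 the apical shaft `apdend1`..`apdend13`
#' (one level per compartment), and levels 19--20 the apical tuft (two
#' compartments at level 19, the terminal one at 20).  The mapping is a named
#' integer vector and can be overridden wherever a `level_map` argument is
#' accepted.
#'
#' @return Named integer vector, names are compartment ids.
#' @export
default_level_map <- function() {
  ids <- c("axon1", "axon2", "soma", paste0("basal", 1:3),
           paste0("apdend", 1:13), paste0("tuft", 1:3))
  lv <- c(0L, 1L, 2L, 3L, 4L, 5L, 6:18, 19L, 19L, 20L)
  stats::setNames(lv, ids)
}

#' Level of a compartment
#'
#' @param compartment_id Character vector of compartment ids.
#' @param level_map Named integer vector, default [default_level_map()].
#' @return Integer vector of levels.
#' @export
#' @examples
#' level_for_compartment("soma")      # 2
#' level_for_compartment("apdend12")  # 17
level_for_compartment <- function(compartment_id,
                                  level_map = default_level_map()) {
  unknown <- setdiff(compartment_id, names(level_map))
  if (length(unknown))
    stop("unknown compartment id(s): ", paste(unknown, collapse = ", "))
  unname(level_map[compartment_id])
}

#' Build the compartment table of the reduced morphology
#'
#' Assembles per-compartment geometry into a data.frame with one row per
#' compartment: id, parent id, level, length and diameter (um), membrane
#' area (cm^2) and `start_distance`, the distance (um) from the soma to the
#' beginning of the compartment measured along the soma-apical axis (`NA`
#' for basal and axonal compartments, which do not lie on that axis).
#' Topology is a tree rooted at the soma: soma -> apical shaft -> tuft,
#' soma -> basal chain, soma -> axon chain.
#'
#' @param geometry Geometry block, default [geometry_defaults()].
#' @param level_map Level assignment, default [default_level_map()].
#' @return data.frame with columns id, parent, level, length_um, diam_um,
#'   area_cm2, start_distance.
#' @export
build_morphology <- function(geometry = geometry_defaults(),
                             level_map = default_level_map()) {
  g <- geometry
  napi <- g$apical$n
  taper <- if (napi > 1) {
    g$apical$diam_base + (g$apical$diam_tip - g$apical$diam_base) *
      (seq_len(napi) - 1) / (napi - 1)
  } else g$apical$diam_base

  id <- c("soma",
          paste0("apdend", seq_len(napi)),
          paste0("tuft", seq_len(g$tuft$n)),
          paste0("basal", seq_len(g$basal$n)),
          paste0("axon", seq_len(g$axon$n)))
  parent <- c(NA,
              c("soma", paste0("apdend", seq_len(napi - 1))),
              c("apdend13", paste0("tuft", seq_len(g$tuft$n - 1))),
              c("soma", paste0("basal", seq_len(g$basal$n - 1))),
              c("soma", paste0("axon", seq_len(g$axon$n - 1))))
  len <- c(g$soma$length,
           rep(g$apical$length, napi),
           rep(g$tuft$length, g$tuft$n),
           rep(g$basal$length, g$basal$n),
           rep(g$axon$length, g$axon$n))
  diam <- c(g$soma$diam, taper,
            rep(g$tuft$diam, length.out = g$tuft$n),
            rep(g$basal$diam, length.out = g$basal$n),
            rep(g$axon$diam, length.out = g$axon$n))
  shaft_len <- napi * g$apical$length
  start <- c(0,
             (seq_len(napi) - 1) * g$apical$length,
             shaft_len + (seq_len(g$tuft$n) - 1) * g$tuft$length,
             rep(NA_real_, g$basal$n + g$axon$n))

  morph <- data.frame(
    id = id, parent = parent,
    level = level_for_compartment(id, level_map),
    length_um = len, diam_um = diam,
    area_cm2 = pi * diam * len * 1e-8,
    start_distance = start,
    stringsAsFactors = FALSE
  )
  rownames(morph) <- morph$id
  morph
}
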