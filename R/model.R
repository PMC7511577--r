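#' Passive membrane parameters
#'
#' Membrane capacitance (uF/cm^2), axial resistivity (Ohm cm), uniform leak
#' density (mS/cm^2), leak reversal (mV), and the global density scale
#' factor applied to every entry of the conductance density table.  The
#' density table is treated as relative densities: `density_scale` maps them
#' onto absolute mS/cm^2.  `density_scale`, `g_leak` and `e_leak` (together
#' with the soma/apical diameters in [geometry_defaults()]) are calibration
#' parameters, jointly fitted so that one passive parameterization
#' reproduces the six target input resistances of the three models at the
#' two 4 Hz injection sites and the subthreshold resting-potential range
#' (see [calibrate_passive()] and the methods vignette).  All values are
#' overridable via the `passive` argument of [build_model()].
#'
#' @return Named list of passive parameters.
#' @export
passive_defaults <- function() {
  list(
    cm = 0.9,                 # uF/cm^2
    ra = 102.546,             # Ohm cm (calibrated)
    g_leak = 0.0851567,       # mS/cm^2 (calibrated)
    e_leak = -84.9959,        # mV (calibrated)
    density_scale = 0.203314  # maps table densities to mS/cm^2 (calibrated)
  )
}

.ih_columns <- c(exp_gradient = "g_h_exp", uniform = "g_h_unif",
                 none = "g_h_0")

#' Build one of the three model neurons
#'
#' Constructs a complete model specification: shared morphology, shared
#' non-Ih conductance densities, and the Ih density column selected by
#' `ih_mode`.  The three modes differ *only* in the Ih column:
#' `"exp_gradient"` (density rising exponentially along the soma-apical
#' axis), `"uniform"`, or `"none"`.
#'
#' @param ih_mode One of `"exp_gradient"`, `"uniform"`, `"none"`.
#' @param passive Passive parameter overrides; a list merged over
#'   [passive_defaults()].
#' @param geometry Geometry block, default [geometry_defaults()].
#' @param kinetics Kinetics configuration, default [kinetics_defaults()].
#' @param conductances Density table, default [conductance_table()].
#' @param level_map Level assignment, default [default_level_map()].
#' @return An object of class `ih_model`: a list with the morphology
#'   data.frame (`$morphology`), per-compartment absolute conductances in uS
#'   (`$g_uS`, channels x compartments), capacitances in nF (`$cm_nF`),
#'   axial couplings to each parent in uS (`$g_ax_uS`), leak conductances
#'   (`$g_leak_uS`), and the full configuration used.
#' @export
#' @examples
#' m <- build_model("uniform")
#' m$g_uS["h", "apdend13"] > m$g_uS["h", "soma"] * 0  # uniform density
build_model <- function(ih_mode = c("exp_gradient", "uniform", "none"),
                        passive = NULL,
                        geometry = geometry_defaults(),
                        kinetics = kinetics_defaults(),
                        conductances = conductance_table(),
                        level_map = default_level_map()) {
  ih_mode <- match.arg(ih_mode)
  p <- passive_defaults()
  if (!is.null(passive)) {
    unknown <- setdiff(names(passive), names(p))
    if (length(unknown))
      stop("unknown passive parameter(s): ", paste(unknown, collapse = ", "))
    p[names(passive)] <- passive
  }
  validate_conductance_table(conductances)
  morph <- build_morphology(geometry, level_map)

  # per-compartment density lookup (mS/cm^2 after global scaling)
  row_of_level <- match(morph$level, conductances$level)
  if (anyNA(row_of_level))
    stop("level/compartment mapping gap: no table row for level(s) ",
         paste(unique(morph$level[is.na(row_of_level)]), collapse = ", "))
  cols <- c(.channel_density_column, h = unname(.ih_columns[ih_mode]))
  dens <- sapply(cols, function(cn) conductances[[cn]][row_of_level])
  dens <- t(dens) * p$density_scale            # channels x comps, mS/cm^2
  colnames(dens) <- morph$id
  rownames(dens) <- names(cols)

  area <- morph$area_cm2
  g_uS <- sweep(dens, 2, area * 1000, `*`)     # mS/cm^2 * cm^2 -> uS
  cm_nF <- p$cm * area * 1000                  # uF/cm^2 * cm^2 -> nF
  g_leak_uS <- p$g_leak * area * 1000

  # axial conductance between each compartment and its parent:
  # series half-cylinder resistances, Ra in Ohm cm, lengths/radii in cm
  g_ax_uS <- numeric(nrow(morph))
  for (i in seq_len(nrow(morph))) {
    if (is.na(morph$parent[i])) next
    j <- match(morph$parent[i], morph$id)
    half_r <- function(k) {
      L <- morph$length_um[k] * 1e-4 / 2
      a <- pi * (morph$diam_um[k] * 1e-4 / 2)^2
      p$ra * L / a
    }
    g_ax_uS[i] <- 1e6 / (half_r(i) + half_r(j))
  }

  structure(list(
    ih_mode = ih_mode,
    morphology = morph,
    passive = p,
    geometry = geometry,
    kinetics = kinetics,
    conductances = conductances,
    densities = dens,
    g_uS = g_uS,
    cm_nF = stats::setNames(cm_nF, morph$id),
    g_leak_uS = stats::setNames(g_leak_uS, morph$id),
    g_ax_uS = stats::setNames(g_ax_uS, morph$id)
  ), class = "ih_model")
}

#' @export
print.ih_model <- function(x, ...) {
  cat("<ih_model>", x$ih_mode, "Ih distribution;",
      nrow(x$morphology), "compartments;",
      "kinetics", x$kinetics$version, "\n")
  cat("  density scale", x$passive$density_scale,
      "| g_leak", x$passive$g_leak, "mS/cm^2",
      "| E_leak", x$passive$e_leak, "mV\n")
  invisible(x)
}

#' Compartment ids along the soma-apical axis
#'
#' Soma, apical shaft and tuft compartments ordered by distance from the
#' soma — the axis along which coupling profiles are reported.
#'
#' @param model An `ih_model`.
#' @return Character vector of compartment ids.
#' @export
apical_axis <- function(model) {
  m <- model$morphology[!is.na(model$morphology$start_distance), ]
  m$id[order(m$start_distance)]
}

# Flatten a model into the arrays the compiled integrator consumes.
# Gate kinetics are tabulated on a fine voltage grid; the integrator
# interpolates linearly.
pack_model <- function(model, v_grid = seq(-250, 60, by = 0.1)) {
  morph <- model$morphology
  n <- nrow(morph)
  parent0 <- match(morph$parent, morph$id) - 1L
  parent0[is.na(parent0)] <- -1L
  # morphology rows are ordered parent-before-child (soma first, chains
  # outward), which the Hines elimination relies on
  stopifnot(all(parent0 < seq_len(n) - 1L))

  kin <- model$kinetics
  chans <- kin$channels
  chan_names <- rownames(model$g_uS)
  rev <- kin$reversals
  gate_chan <- integer(0); gate_power <- numeric(0)
  inf_tab <- NULL; tau_tab <- NULL
  for (ci in seq_along(chan_names)) {
    ch <- chans[[chan_names[ci]]]
    for (g in ch$gates) {
      gate_chan <- c(gate_chan, ci - 1L)
      gate_power <- c(gate_power, g$power)
      inf_tab <- cbind(inf_tab, gate_steady_state(g, v_grid))
      tau_tab <- cbind(tau_tab, gate_time_constant(g, v_grid))
    }
  }
  list(
    n = n,
    ids = morph$id,
    parent = parent0,
    cm = unname(model$cm_nF),
    g_ax = unname(model$g_ax_uS),
    g_leak = unname(model$g_leak_uS),
    e_leak = model$passive$e_leak,
    chan_g = t(model$g_uS),                      # comps x channels
    chan_e = vapply(chan_names,
                    function(cn) unname(rev[[chans[[cn]]$reversal]]), 0),
    chan_ca_gated = vapply(chan_names,
                           function(cn) isTRUE(chans[[cn]]$ca_gated), TRUE),
    chan_is_ca = vapply(chan_names,
                        function(cn) isTRUE(chans[[cn]]$ca_current), TRUE),
    gate_chan = gate_chan,
    gate_power = gate_power,
    gate_inf = inf_tab,
    gate_tau = tau_tab,
    v_min = v_grid[1],
    dv = v_grid[2] - v_grid[1],
    ca_gain = kin$ca_pool$gain,
    ca_tau = kin$ca_pool$tau,
    ca_kd = kin$ca_pool$kd
  )
}
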