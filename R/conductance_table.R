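#' Membrane conductance density table for the three model neurons
#'
#' Returns the per-level membrane conductance densities used by all three
#' model configurations.  Rows are morphological levels 0--20 of the reduced
#' pyramidal-neuron structure; columns are channel density values (relative
#' densities, multiplied by the global `density_scale` passive parameter when
#' a model is built; see [passive_defaults()]).  The three rightmost columns
#' are the alternative Ih distributions: `g_h_exp` (exponential somato-apical
#' gradient), `g_h_unif` (uniform), and `g_h_0` (no Ih).  All other columns
#' are shared by the three models.  Fast sodium `g_NaF` is zero at every
#' level: the models are deliberately non-spiking and the study is
#' subthreshold.
#'
#' @return A data.frame with 21 rows (column `level` = 0..20) and 12 density
#'   columns.
#' @seealso [read_conductance_table()] for reading the same table from CSV,
#'   [build_model()] which consumes it.
#' @export
#' @examples
#' tab <- conductance_table()
#' tab[tab$level == 20, "g_h_exp"]  # strongest distal Ih density
conductance_table <- function() {
  tab <- data.frame(
    level = 0:20,
    g_NaF = rep(0, 21),
    g_NaP = c(5, 5, 5, 0.6, 0.12, 0.12, 1.2, 0.6, 0.12, 0.12, 0.12, 0.12,
              0.12, 0.12, 0.12, 0.024, 0.024, 0.024, 0.024, 0.024, 0.024),
    g_KDR = c(450, 450, 750, 250, 0, 0, 500, 150, 2, 2, 2, 2, 2, 2, 2, 2,
              2, 2, 2, 2, 2),
    g_KC  = c(0, 0, 288, 288, 9, 9, 288, 288, 9, 9, 9, 9, 9, 9, 9, 9, 9,
              9, 9, 9, 9),
    g_KA  = c(6, 6, 200, 40, 40, 40, 40, 40, 40, 40, 40, 40, 40, 40, 40,
              40, 40, 40, 40, 40, 40),
    g_KM  = c(600, 300, 250, 136, 136, 136, 136, 136, 136, 40, 40, 40, 40,
              40, 40, 40, 10, 10, 10, 10, 10),
    g_K2  = c(15, 15, 15, 0, 0, 0, 15, 15, 15, 0, 0, 0, 0, 0, 0, 0, 10,
              10, 10, 10, 10),
    g_CaH = c(0, 0, 16, 16, 16, 16, 16, 16, 16, 4, 4, 4, 4, 4, 4, 4, 4, 4,
              4, 10.8, 2.4),
    g_CaL = c(0, 0, rep(1, 19)),
    g_h_exp = c(0, 0, 1, 1.7635, 2.4515, 3.3194, 1.7635, 2.4515, 3.3194,
                4.4141, 5.7950, 7.5368, 9.7338, 12.5050, 16.0006, 20.4098,
                25.9714, 32.9866, 41.8355, 52.9971, 52.9971),
    g_h_unif = c(0, 0, rep(1, 17), 2, 2),
    g_h_0 = rep(0, 21)
  )
  validate_conductance_table(tab)
  tab
}

.density_columns <- c("g_NaF", "g_NaP", "g_KDR", "g_KC", "g_KA", "g_KM",
                      "g_K2", "g_CaH", "g_CaL", "g_h_exp", "g_h_unif",
                      "g_h_0")

#' Read a conductance density table from CSV
#'
#' Reads a table in the same layout as [conductance_table()] (a `level`
#' column plus the 12 density columns) and validates it.  The packaged copy
#' lives at `system.file("extdata", "conductance_table.csv", package =
#' "ihcfc")`.
#'
#' @param path Path to a CSV file.
#' @return A validated data.frame, as [conductance_table()].
#' @export
read_conductance_table <- function(path) {
  tab <- utils::read.csv(path, check.names = TRUE)
  validate_conductance_table(tab)
  tab[order(tab$level), , drop = FALSE]
}

#' Validate a conductance density table
#'
#' Checks the structural contract: 21 levels (0--20) each present exactly
#' once, exactly the 12 expected density columns, and no negative or missing
#' densities.  Errors name the offending row/column.
#'
#' @param tab A data.frame as returned by [conductance_table()].
#' @return Invisibly, `tab`.
#' @export
validate_conductance_table <- function(tab) {
  if (!is.data.frame(tab) || !"level" %in% names(tab))
    stop("conductance table must be a data.frame with a 'level' column")
  missing_cols <- setdiff(.density_columns, names(tab))
  if (length(missing_cols))
    stop("conductance table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(tab), c("level", .density_columns))
  if (length(extra))
    stop("conductance table has unexpected column(s): ",
         paste(extra, collapse = ", "))
  if (!setequal(tab$level, 0:20) || nrow(tab) != 21L)
    stop("conductance table must contain each level 0..20 exactly once; ",
         "missing: ", paste(setdiff(0:20, tab$level), collapse = ", "))
  for (cn in .density_columns) {
    v <- tab[[cn]]
    if (anyNA(v))
      stop("NA density in column ", cn, " at level ",
           paste(tab$level[is.na(v)], collapse = ", "))
    if (any(v < 0))
      stop("negative density in column ", cn, " at level ",
           paste(tab$level[v < 0], collapse = ", "))
  }
  invisible(tab)
}
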