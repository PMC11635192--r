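#' Grid search over the two conductance DACs
#'
#' Runs the full attenuation protocol at every point of a rectangular grid of
#' `(g_l DAC, g_ic DAC)` codes and records the fitted length constant and the
#' first-compartment amplitude.  Each cell uses a fresh recording-noise seed
#' (independent runs, as on hardware).  Cells whose attenuation fit is
#' degenerate are flagged in `failed_cells` and carry `NA` in the maps — they
#' are never silently filled.
#'
#' @param substrate_cfg a [substrate_config()].
#' @param protocol_cfg a [protocol_config()].
#' @param gl_values integer DAC codes for the leak-conductance axis.
#' @param gic_values integer DAC codes for the inter-compartment axis.
#' @param seed master seed; cell `(i, j)` uses the derived stream
#'   `"cell<i>-<j>"`.
#' @param noise_sigma recording noise SD; defaults to the substrate config
#'   (set 0 for a noiseless sweep).
#' @return an object of class `grid_result`: `dac_axis_gl`, `dac_axis_gic`,
#'   `lambda_map` and `h0_map` (matrices `length(gl) x length(gic)`), and
#'   `failed_cells` (data frame of degenerate grid points).
#' @export
grid_sweep <- function(substrate_cfg = substrate_config(),
                       protocol_cfg = protocol_config(),
                       gl_values = round(seq(0, DAC_MAX, length.out = 32)),
                       gic_values = round(seq(0, DAC_MAX, length.out = 32)),
                       seed = 0L, noise_sigma = substrate_cfg$noise_sigma) {
  if (!length(gl_values) || !length(gic_values))
    config_error("grid axes must be non-empty")
  nl <- length(gl_values)
  ni <- length(gic_values)
  lambda_map <- matrix(NA_real_, nl, ni)
  h0_map <- matrix(NA_real_, nl, ni)
  failed <- list()
  for (i in seq_len(nl)) {
    for (j in seq_len(ni)) {
      cell_seed <- derive_seed(seed, paste0("cell", i, "-", j))
      obs <- tryCatch(
        run_attenuation_experiment(c(gl_values[i], gic_values[j]),
                                   substrate_cfg, protocol_cfg,
                                   seed = cell_seed,
                                   noise_sigma = noise_sigma),
        evochain_degenerate_fit = function(e) e)
      if (inherits(obs, "condition")) {
        failed[[length(failed) + 1L]] <-
          data.frame(gl_dac = gl_values[i], gic_dac = gic_values[j],
                     reason = conditionMessage(obs))
      } else {
        lambda_map[i, j] <- obs$lambda_emp
        h0_map[i, j] <- obs$h0
      }
    }
  }
  structure(list(dac_axis_gl = gl_values, dac_axis_gic = gic_values,
                 lambda_map = lambda_map, h0_map = h0_map,
                 failed_cells = if (length(failed)) do.call(rbind, failed)
                                else data.frame(gl_dac = integer(),
                                                gic_dac = integer(),
                                                reason = character()),
                 seed = seed),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d x %d grid, %d degenerate cells\n",
              length(x$dac_axis_gl), length(x$dac_axis_gic),
              nrow(x$failed_cells)))
  cat(sprintf("  lambda_emp range: [%.3f, %.3f] compartments\n",
              min(x$lambda_map, na.rm = TRUE), max(x$lambda_map, na.rm = TRUE)))
  invisible(x)
}

#' Fitness landscape over a grid-search result
#'
#' Applies the two-observable fitness [fitness_lambda_amplitude()] cell-wise
#' to the grid's length-constant and amplitude maps.  Degenerate cells carry
#' the worst-case sentinel `1e6`.
#'
#' @param grid a `grid_result`.
#' @param target a [target_observation()] with `lambda_hat` and `h0_hat`.
#' @return numeric matrix of `f2` values, same shape as the grid maps.
#' @export
fitness_landscape <- function(grid, target) {
  stopifnot(!is.null(target$lambda_hat), !is.null(target$h0_hat))
  f2 <- ((target$lambda_hat - grid$lambda_map) / target$lambda_hat)^2 +
    ((target$h0_hat - grid$h0_map) / target$h0_hat)^2
  f2[is.na(f2)] <- WORST_FITNESS
  f2
}

#' Iso-level contour of the length-constant map
#'
#' Traces the contour of `lambda_map` at a given level in DAC coordinates
#' (marching squares with linear interpolation along cell edges, via
#' [grDevices::contourLines()]); e.g. the locus of DAC pairs realizing a
#' target length constant.
#'
#' @param grid a `grid_result` (axes must be strictly increasing).
#' @param level the `lambda_emp` level to trace.
#' @return list of contour segments, each a data frame with `gl_dac` and
#'   `gic_dac`; empty if the level is outside the map range (or the map is
#'   constant).
#' @export
iso_lambda_contour <- function(grid, level) {
  z <- grid$lambda_map
  rng <- range(z, na.rm = TRUE)
  if (!is.finite(level) || level <= rng[1] || level >= rng[2]) return(list())
  cl <- grDevices::contourLines(x = as.numeric(grid$dac_axis_gl),
                                y = as.numeric(grid$dac_axis_gic),
                                z = z, levels = level)
  lapply(cl, function(seg)
    data.frame(gl_dac = seg$x, gic_dac = seg$y))
}

#' Export a grid-search result as CSV matrices plus JSON metadata
#'
#' Writes `<path>_lambda.csv` and `<path>_h0.csv` (axis codes as header row
#' and first column) and `<path>.json` (axes, seed, failed cells).
#'
#' @param grid a `grid_result`.
#' @param path output path stem.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  dump_map <- function(map, file) {
    df <- as.data.frame(map)
    names(df) <- paste0("gic_", grid$dac_axis_gic)
    df <- cbind(gl_dac = grid$dac_axis_gl, df)
    write.csv(df, file, row.names = FALSE)
  }
  dump_map(grid$lambda_map, paste0(path, "_lambda.csv"))
  dump_map(grid$h0_map, paste0(path, "_h0.csv"))
  jsonlite::write_json(
    list(dac_axis_gl = grid$dac_axis_gl, dac_axis_gic = grid$dac_axis_gic,
         seed = grid$seed, failed_cells = grid$failed_cells),
    paste0(path, ".json"), pretty = TRUE, digits = NA)
  invisible(path)
}
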