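# Run configuration: a human-readable YAML key tree covering geometry,
# layout, discretization, physical parameters, ionic model, channel
# distribution, stimulus and probes.  All lengths are given in um (nm
# accepted via the `*_nm` spellings) and normalised to cm on load; the
# package defaults are the simulator's standard parameter set.

.config_defaults <- function() {
  list(
    geometry = list(size_O = c(100, 18, 18), size_WE = c(2, 14, 14),
                    size_SN = c(14, 2, 14)),
    layout = list(n_cells = 1, padding = c(10, 10, 4), gap = 0),
    grid = list(dx = 1, dy = 1, dz = 2, cleft_dx = NULL),
    time = list(dt = 0.001, t_end = 10),
    params = list(sigma_i = 4, sigma_e = 20, C_m = 1, C_disc = 0.5,
                  R_g = 0.0045, rg_factor = 1),
    model = "grandi_epicardial",
    distribution = list(p = 0, region = "horizontal_ends"),
    stimulus = list(amplitude = 80, duration = 1, onset = 0,
                    cells = c(1, 2)),
    record_every = 1
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML document (or takes a list), rejects unknown keys, fills in
#' the defaults, and validates ranges and dimensional consistency.  An
#' empty document yields the default configuration.
#'
#' @param x path to a YAML file, a YAML string, or a list.
#' @return A validated configuration list of class `emi_config`.
#' @export
load_config <- function(x = list()) {
  if (is.character(x)) {
    x <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
    if (is.null(x)) x <- list()
  }
  if (!is.list(x)) stop("configuration must be a YAML mapping")
  def <- .config_defaults()
  unknown <- setdiff(names(x), names(def))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  merge1 <- function(d, u, path) {
    if (is.null(u)) return(d)
    if (!is.list(d)) return(u)
    bad <- setdiff(names(u), names(d))
    if (length(bad)) {
      stop("unknown configuration key(s): ",
           paste(paste0(path, "$", bad), collapse = ", "))
    }
    for (nm in names(u)) {
      val <- merge1(d[[nm]], u[[nm]], paste0(path, "$", nm))
      if (is.null(val)) d[nm] <- list(NULL) else d[[nm]] <- val
    }
    d
  }
  cfg <- merge1(def, x, "")
  ck <- function(cond, msg) if (!cond) stop("invalid configuration: ", msg)
  ck(all(unlist(cfg$geometry) >= 0), "geometry sizes must be >= 0")
  ck(cfg$layout$n_cells >= 1, "layout$n_cells must be >= 1")
  ck(all(cfg$layout$padding > 0), "layout$padding must be positive")
  ck(all(c(cfg$grid$dx, cfg$grid$dy, cfg$grid$dz) > 0),
     "grid spacings must be positive")
  ck(cfg$time$dt > 0 && cfg$time$t_end > 0, "time steps must be positive")
  with(cfg$params, {
    ck(sigma_i > 0 && sigma_e > 0, "conductivities must be positive")
    ck(C_m > 0 && C_disc > 0, "capacitances must be positive")
    ck(R_g > 0, "R_g must be positive")
  })
  ck(cfg$distribution$p >= 0 && cfg$distribution$p <= 1,
     "distribution$p must lie in [0, 1]")
  ck(cfg$distribution$region %in% c("horizontal_ends", "vertical_ends"),
     "unknown distribution$region")
  ck(cfg$model %in% c("grandi_epicardial", "reduced"),
     paste("unknown ionic model:", cfg$model))
  class(cfg) <- "emi_config"
  cfg
}

#' Instantiate the pieces of a configuration
#'
#' @param cfg an `emi_config`.
#' @return list(mesh, model, gna, params, stimulus, dt, t_end)
#' @export
config_build <- function(cfg) {
  mesh <- build_strand(
    cell_geometry(cfg$geometry$size_O, cfg$geometry$size_WE,
                  cfg$geometry$size_SN),
    strand_layout(cfg$layout$n_cells, cfg$layout$padding, cfg$layout$gap),
    grid_spec(cfg$grid$dx, cfg$grid$dy, cfg$grid$dz, cfg$grid$cleft_dx))
  model <- switch(cfg$model,
                  grandi_epicardial = grandi_epicardial(),
                  reduced = reduced_test_model())
  gna <- assign_gna(mesh,
                    channel_distribution(cfg$distribution$p,
                                         cfg$distribution$region),
                    model)
  params <- emi_params(cfg$params$sigma_i, cfg$params$sigma_e,
                       cfg$params$C_m, cfg$params$C_disc,
                       cfg$params$R_g, cfg$params$rg_factor)
  stim <- stimulus_protocol(cfg$stimulus$amplitude, cfg$stimulus$duration,
                            cfg$stimulus$onset, cfg$stimulus$cells)
  list(mesh = mesh, model = model, gna = gna, params = params,
       stimulus = stim, dt = cfg$time$dt, t_end = cfg$time$t_end,
       record_every = cfg$record_every)
}

#' Run a simulation from a configuration
#'
#' @param cfg an `emi_config` (or anything [load_config()] accepts).
#' @return An `emi_result`.
#' @export
run_config <- function(cfg) {
  if (!inherits(cfg, "emi_config")) cfg <- load_config(cfg)
  pieces <- config_build(cfg)
  emi_run(pieces$mesh, pieces$model, pieces$gna, pieces$params,
          t_end = pieces$t_end, dt = pieces$dt,
          stimulus = pieces$stimulus,
          record_every = pieces$record_every)
}
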