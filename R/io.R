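# File formats, config validation and the umbrella pipeline.
#
# All tabular I/O is plain CSV with unit-suffixed headers; configs are
# JSON. Every pipeline run writes a manifest recording the command, the
# options with defaults filled in, the seed, md5 hashes of every input
# file, and the package version, so outputs are traceable to inputs.
# Angles are degrees at file interfaces, radians internally.

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stopf("malformed CSV '%s': %s", path,
                                           conditionMessage(e)))
  miss <- setdiff(required, names(df))
  if (length(miss)) stopf("%s file '%s' lacks column(s): %s", what, path,
                          paste(miss, collapse = ", "))
  df
}

#' Read a waveform/protocol table
#'
#' Columns: `label`, `kind`, `rest_s`, `n_group`, `peak_strain_ue`, `N`,
#' `d`, plus the kind-specific timings (`rise_s`, `hold_s`, `fall_s`,
#' `frequency_hz`, `duration_s`; unused ones may be blank).
#'
#' @param path CSV path
#' @return named list of [loading_protocol()] objects
#' @export
read_protocols_csv <- function(path) {
  df <- read_csv_checked(path, c("label", "kind", "peak_strain_ue", "N", "d"),
                         "protocol")
  g <- function(row, nm) {
    v <- df[[nm]]
    if (is.null(v) || is.na(v[row])) NULL else v[row]
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    sp <- list(rise_s = g(i, "rise_s"), hold_s = g(i, "hold_s"),
               fall_s = g(i, "fall_s"), frequency_hz = g(i, "frequency_hz"),
               duration_s = g(i, "duration_s"))
    sp <- sp[!vapply(sp, is.null, TRUE)]
    wf <- make_waveform(df$kind[i], sp, rest_s = g(i, "rest_s") %||% 0,
                        n_group = g(i, "n_group") %||% 1L)
    loading_protocol(df$label[i], wf, df$peak_strain_ue[i], df$N[i], df$d[i])
  })
  names(out) <- df$label
  out
}

#' Read a cell/edge network from CSV files
#'
#' Cells CSV: `id,kind,x_um,y_um,surface`. Edges CSV: `id_a,id_b` and
#' optional `length_um` (blank = Euclidean), `area_um2`.
#'
#' @param cells_path,edges_path CSV paths
#' @param A0_um2 default process area
#' @return a [cell_network()]
#' @export
read_network_csv <- function(cells_path, edges_path, A0_um2 = 0.025) {
  cells <- read_csv_checked(cells_path, c("id", "kind", "x_um", "y_um"), "cells")
  edges <- read_csv_checked(edges_path, c("id_a", "id_b"), "edges")
  cell_network(cells, edges, A0_um2 = A0_um2)
}

#' Read a cross-section from boundary-vertex CSV files
#'
#' Each CSV has columns `x_um,y_um`, vertices in order.
#'
#' @param periosteal_path,endocortical_path CSV paths (endocortical optional)
#' @return a [section_properties()] `cross_section`
#' @export
read_section_csv <- function(periosteal_path, endocortical_path = NULL) {
  po <- read_csv_checked(periosteal_path, c("x_um", "y_um"), "periosteal polygon")
  pe <- if (!is.null(endocortical_path))
    read_csv_checked(endocortical_path, c("x_um", "y_um"), "endocortical polygon")
  section_properties(as.matrix(po[, c("x_um", "y_um")]),
                     if (is.null(pe)) NULL else as.matrix(pe[, c("x_um", "y_um")]))
}

write_params_json <- function(params, path, extra = list()) {
  x <- c(unclass(params)[!vapply(unclass(params), is.null, TRUE)], extra)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_params_json <- function(path) {
  if (!file.exists(path)) stopf("parameter file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # [[ ]] avoids partial matching (x$p would match p_d_beta)
  model_parameters(q = x[["q"]], eps_thres = x[["eps_thres"]],
                   r_s = x[["r_s"]] %||% 0, p = x[["p"]], beta = x[["beta"]],
                   p_d_beta = x[["p_d_beta"]], h = x[["h"]],
                   D_cm2_s = x[["D_cm2_s"]] %||% 5.3e-6,
                   A0_um2 = x[["A0_um2"]] %||% 0.025, k = x[["k"]])
}

.config_keys <- c("seed", "out_dir", "section", "endocortical", "cells",
                  "edges", "protocols", "observations", "params", "problem",
                  "options")
.config_defaults <- list(seed = 1L, options = list())
.file_keys <- c("section", "endocortical", "cells", "edges", "protocols",
                "observations", "params", "problem")

#' Load and validate a pipeline configuration
#'
#' Reads a JSON config, rejects unknown keys, fills defaults (recorded in
#' the manifest), resolves file paths relative to the config location and
#' checks the referenced files exist.
#'
#' @param config_path path to a JSON config
#' @return object of class `run_config`
#' @export
load_and_validate <- function(config_path) {
  if (!file.exists(config_path)) stopf("config file not found: %s", config_path)
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  filled <- character(0)
  for (k in names(.config_defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- .config_defaults[[k]]
      filled <- c(filled, k)
    }
  }
  base <- dirname(normalizePath(config_path))
  for (k in intersect(.file_keys, names(cfg))) {
    p <- cfg[[k]]
    if (!file.exists(p)) p <- file.path(base, cfg[[k]])
    if (!file.exists(p)) stopf("config key '%s': file not found: %s", k, cfg[[k]])
    cfg[[k]] <- normalizePath(p)
  }
  cfg$defaults_filled <- filled
  cfg$config_path <- normalizePath(config_path)
  structure(cfg, class = "run_config")
}

#' Run a pipeline command
#'
#' Dispatches one of `make-fixture`, `fit-average`, `predict-average`,
#' `invert-strain`, `invert-cycles`, `forward-site`, `calibrate-k`,
#' `invert-loads`, `compare` over a validated config, writes its outputs
#' plus `manifest.json` into `out_dir`, and returns the output paths.
#'
#' @param config a [load_and_validate()] `run_config`
#' @param command command name, see above
#' @param out_dir output directory (default `config$out_dir` or a tempdir)
#' @return named list of output file paths, invisibly
#' @export
run_pipeline <- function(config, command, out_dir = NULL) {
  if (!inherits(config, "run_config")) stopf("'config' must be a run_config")
  commands <- c("make-fixture", "fit-average", "predict-average",
                "invert-strain", "invert-cycles", "forward-site",
                "calibrate-k", "invert-loads", "compare")
  if (!command %in% commands)
    stopf("unknown command '%s' (expected one of: %s)", command,
          paste(commands, collapse = ", "))
  out_dir <- out_dir %||% config$out_dir %||% tempfile("osteoadapt_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opts <- config$options
  outputs <- list()
  put <- function(name, path) { outputs[[name]] <<- path; path }

  if (command == "make-fixture") {
    spec <- do.call(fixture_spec, c(opts$fixture %||% list(),
                                    list(seed = config$seed)))
    sec <- make_section(spec)
    net <- make_cells_and_network(sec, spec)
    utils::write.csv(as.data.frame(sec$periosteal_um),
                     put("section", file.path(out_dir, "section_periosteal.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(sec$endocortical_um),
                     put("endocortical", file.path(out_dir, "section_endocortical.csv")),
                     row.names = FALSE)
    utils::write.csv(net$cells, put("cells", file.path(out_dir, "cells.csv")),
                     row.names = FALSE)
    utils::write.csv(net$edges, put("edges", file.path(out_dir, "edges.csv")),
                     row.names = FALSE)
  } else if (command == "fit-average") {
    prot <- read_protocols_csv(config$protocols)
    obs <- read_csv_checked(config$observations, c("label", "B0"), "observations")
    fit <- fit_average_model(prot, obs,
                             free = opts$free %||% c("p_d_beta", "q", "r_s", "eps_thres"),
                             n_starts = opts$n_starts %||% 5L,
                             seed = config$seed)
    write_params_json(fit$params, put("params", file.path(out_dir, "params.json")),
                      extra = list(objective = fit$objective,
                                   converged = fit$converged,
                                   flags = fit$flags))
  } else if (command == "predict-average") {
    prot <- read_protocols_csv(config$protocols)
    params <- read_params_json(config$params)
    pred <- data.frame(label = names(prot),
                       B_um3_um2_day = vapply(prot, function(pr)
                         bfr_forward(params, pr), 0))
    utils::write.csv(pred, put("predictions", file.path(out_dir, "predictions.csv")),
                     row.names = FALSE)
  } else if (command %in% c("invert-strain", "invert-cycles")) {
    params <- read_params_json(config$params)
    wf <- read_protocols_csv(config$protocols)[[opts$protocol %||% 1L]]
    xi <- protocol_xi(wf$waveform, params$r_s)$xi
    res <- if (command == "invert-strain")
      list(eps_peak_ue = invert_peak_strain(opts$B_target, params,
                                            opts$N %||% wf$N, opts$d %||% wf$d, xi))
    else invert_cycles(opts$B_target, params, opts$eps_peak,
                       opts$d %||% wf$d, xi)
    jsonlite::write_json(c(res, list(xi = xi)),
                         put("result", file.path(out_dir, "inversion.json")),
                         auto_unbox = TRUE, digits = NA)
  } else if (command == "forward-site") {
    params <- read_params_json(config$params)
    net <- read_network_csv(config$cells, config$edges,
                            A0_um2 = params$A0_um2)
    sec <- read_section_csv(config$section, config$endocortical)
    wf <- read_protocols_csv(config$protocols)[[opts$protocol %||% 1L]]
    loads <- section_loads(opts$Fz0_N %||% 0, opts$Mx0_Nmm %||% 0,
                           opts$My0_Nmm %||% 0)
    mar <- forward_mar(loads, wf$waveform, wf$N, wf$d, params, params$k,
                       net, sec)
    ob <- net$cells[net$cells$kind == "osteoblast", ]
    tab <- data.frame(osteoblast_id = mar$mar$id,
                      x_um = ob$x_um[match(mar$mar$id, ob$id)],
                      y_um = ob$y_um[match(mar$mar$id, ob$id)],
                      surface = mar$mar$surface,
                      mar_um_per_day = mar$mar$mar_um_day)
    utils::write.csv(tab, put("mar", file.path(out_dir, "mar.csv")),
                     row.names = FALSE)
    jsonlite::write_json(list(xi = mar$xi, gain = mar$gain,
                              bfr_bs = as.list(mar$bfr_bs)),
                         put("summary", file.path(out_dir, "site_summary.json")),
                         auto_unbox = TRUE, digits = NA)
  } else if (command == "calibrate-k") {
    obs <- read_csv_checked(config$observations, c("label", "B0"), "observations")
    q_tab <- read_csv_checked(config$cells, c("label", "q_nmol_day"),
                              "flux table")   # per-protocol fluxes
    q_data <- split(q_tab$q_nmol_day, factor(q_tab$label, obs$label))
    cal <- calibrate_k("multi_avg", obs$B0, q_data)
    jsonlite::write_json(list(k = cal$k, k_magnitude = cal$k_magnitude,
                              mode = cal$mode, objective = cal$objective),
                         put("k", file.path(out_dir, "k.json")),
                         auto_unbox = TRUE, digits = NA)
  } else if (command == "invert-loads") {
    params <- read_params_json(config$params)
    net <- read_network_csv(config$cells, config$edges, A0_um2 = params$A0_um2)
    sec <- read_section_csv(config$section, config$endocortical)
    spec <- jsonlite::read_json(config$problem, simplifyVector = TRUE)
    wf <- read_protocols_csv(config$protocols)[[spec$protocol %||% 1L]]
    prob <- inverse_problem(
      data.frame(id = spec$prescriptions$id,
                 mar0_um_day = spec$prescriptions$mar0_um_day),
      wf$waveform, spec$N %||% wf$N, spec$d %||% wf$d, params, params$k,
      net, sec, B0 = spec$B0, lambda = spec$lambda,
      initial_guess = if (!is.null(spec$initial_guess))
        do.call(section_loads, as.list(spec$initial_guess)) else NULL)
    sol <- solve_inverse(prob, seed = config$seed)
    jsonlite::write_json(list(Fz0_N = sol$loads$Fz0_N,
                              Mx0_Nmm = sol$loads$Mx0_Nmm,
                              My0_Nmm = sol$loads$My0_Nmm,
                              residual = sol$residual,
                              converged = sol$converged,
                              peak_tensile_ue = sol$peak_tensile_ue,
                              peak_compressive_ue = sol$peak_compressive_ue,
                              neutral_axis_deg = sol$neutral_axis_deg),
                         put("loads", file.path(out_dir, "loads.json")),
                         auto_unbox = TRUE, digits = NA)
  } else { # compare
    need <- c("x_um", "y_um", "mar_um_per_day")
    mdl <- read_csv_checked(config$cells, need, "model MAR")
    obs <- read_csv_checked(config$observations, need, "observed MAR")
    da <- mar_to_circular(mdl$x_um, mdl$y_um, mdl$mar_um_per_day)
    db <- mar_to_circular(obs$x_um, obs$y_um, obs$mar_um_per_day)
    tst <- watson_u2(da, db, mode = opts$mode %||% "permutation",
                     n_perm = opts$n_perm %||% 999L, seed = config$seed)
    jsonlite::write_json(list(statistic = tst$statistic, p = tst$p_value,
                              mode = tst$mode),
                         put("test", file.path(out_dir, "compare.json")),
                         auto_unbox = TRUE, digits = NA)
  }

  in_files <- unlist(config[intersect(.file_keys, names(config))],
                     use.names = TRUE)
  if (is.null(in_files)) in_files <- character(0)
  manifest <- list(command = command, seed = config$seed,
                   options = opts, defaults_filled = config$defaults_filled,
                   inputs = as.list(tools::md5sum(in_files)),
                   outputs = lapply(outputs, basename),
                   package_version = as.character(utils::packageVersion("osteoadapt")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs$manifest <- file.path(out_dir, "manifest.json")
  invisible(outputs)
}
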