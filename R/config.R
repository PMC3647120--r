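# Configuration files, experiment runners and the command-line interface.
#
# Configuration is a flat key = value text format (one pair per line, '#'
# comments). Keys are named after the standard parameter symbols; derived
# conductances (g_IS = alpha*g_SI, g_ES = alpha*g_SE, g_EI = alpha*g_IE)
# and kappa_G = 1/(E_L - E_I) are computed from the resolved values unless
# explicitly overridden. Every experiment writes a resolved-parameter dump
# next to its results for provenance.

.config_defaults <- function() {
  list(
    # single neuron (reference table)
    E_L = -70, E_E = 10, E_I = -80, C_S = 740, C_D = 50,
    g_S = 30, g_D = 20, g_SI = 5, g_SE = 10, g_IE = 1, alpha = 5,
    g_IS = NA_real_, g_ES = NA_real_, g_EI = NA_real_,  # derived
    # geometry
    geometry = "on_path", N_branches = 1,
    # synapses / network
    tau_E = 100, tau_I = 10, w_E = 24, w_I = 2,
    N_E = 2000, N_I = 500, p = 0.1, C_S_E = 740, C_S_I = 370,
    E_thres = -50, E_reset = -70, sigma = 2, g_ext = 10,
    stim_onset = 50, stim_offset = 250, dt = 0.1, seed = 1,
    stim_population = "both", include_branch_load = FALSE,
    fixed_in_degree = TRUE,
    # mean-field
    mu_E = 3.2, mu_I = 6.4, beta = 17.5,
    a = 0.002, b = 0.175, c = -0.113, d = -0.6218, kappa_G = NA_real_,
    # distance rule
    g_max = 300, mu_spatial = 3,
    tau_S = NA_real_)  # derived; recomputed on load, accepted in dumps
}

.string_keys <- c("geometry", "stim_population")
.logical_keys <- c("include_branch_load", "fixed_in_degree")

#' Load a configuration file
#'
#' Reads a flat `key = value` configuration (empty lines and `#` comments
#' ignored), applies it on top of the package defaults, computes the
#' derived quantities (`g_IS`, `g_ES`, `g_EI` from `alpha`;
#' `kappa_G = 1/(E_L - E_I)`; the per-geometry `tau_S`), and returns the
#' resolved parameter objects. Unknown keys and malformed numeric values
#' raise errors naming the offenders.
#'
#' @param path path to a configuration file, or `NULL` for pure defaults.
#' @param overrides named list applied after the file (same keys).
#' @return A list with elements `neuron` ([neuron_params()]), `config`
#'   ([dendritic_config()]), `network` ([network_params()]), `meanfield`
#'   ([meanfield_params()]), `distance` ([distance_model()]) and
#'   `resolved` (the full named list, including derived values).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- .config_defaults()
  known <- names(vals)
  apply_kv <- function(key, value, where) {
    if (!key %in% known)
      stop("unknown configuration key", if (nzchar(where)) paste0(" in ", where),
           ": '", key, "'")
    if (key %in% .string_keys) {
      vals[[key]] <<- value
    } else if (key %in% .logical_keys) {
      lv <- toupper(value) %in% c("TRUE", "T", "1", "YES")
      if (!toupper(value) %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO"))
        stop("malformed logical value for key '", key, "': '", value, "'")
      vals[[key]] <<- lv
    } else {
      num <- suppressWarnings(as.numeric(value))
      if (is.na(num))
        stop("malformed numeric value for key '", key, "': '", value, "'")
      vals[[key]] <<- num
    }
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE))
        stop("malformed configuration line (expected key = value): '", ln, "'")
      key <- trimws(sub("=.*$", "", ln))
      value <- trimws(sub("^[^=]*=", "", ln))
      apply_kv(key, value, path)
    }
  }
  for (key in names(overrides))
    apply_kv(key, as.character(overrides[[key]]), "overrides")
  # derived quantities
  if (is.na(vals$g_IS)) vals$g_IS <- vals$alpha * vals$g_SI
  if (is.na(vals$g_ES)) vals$g_ES <- vals$alpha * vals$g_SE
  if (is.na(vals$g_EI)) vals$g_EI <- vals$alpha * vals$g_IE
  if (is.na(vals$kappa_G)) vals$kappa_G <- 1 / (vals$E_L - vals$E_I)
  neuron <- neuron_params(E_L = vals$E_L, E_E = vals$E_E, E_I = vals$E_I,
                          C_S = vals$C_S, C_D = vals$C_D,
                          g_S = vals$g_S, g_D = vals$g_D,
                          g_SI = vals$g_SI, g_SE = vals$g_SE,
                          g_IE = vals$g_IE, alpha = vals$alpha,
                          g_IS = vals$g_IS, g_ES = vals$g_ES,
                          g_EI = vals$g_EI)
  config <- dendritic_config(vals$geometry, vals$N_branches)
  network <- network_params(N_E = vals$N_E, N_I = vals$N_I, p = vals$p,
                            w_E = vals$w_E, w_I = vals$w_I,
                            C_S_E = vals$C_S_E, C_S_I = vals$C_S_I,
                            tau_E = vals$tau_E, tau_I = vals$tau_I,
                            E_thres = vals$E_thres, E_reset = vals$E_reset,
                            sigma = vals$sigma, g_ext = vals$g_ext,
                            stim_onset = vals$stim_onset,
                            stim_offset = vals$stim_offset,
                            dt = vals$dt, seed = vals$seed,
                            fixed_in_degree = vals$fixed_in_degree,
                            stim_population = vals$stim_population,
                            include_branch_load = vals$include_branch_load)
  meanfield <- meanfield_params(mu_E = vals$mu_E, mu_I = vals$mu_I,
                                beta = vals$beta, a = vals$a, b = vals$b,
                                c_ = vals$c, d = vals$d,
                                kappa_G = vals$kappa_G,
                                w_E = vals$w_E, w_I = vals$w_I,
                                tau_E = vals$tau_E, tau_I = vals$tau_I,
                                p = vals$p, N_E = vals$N_E, N_I = vals$N_I)
  vals$tau_S <- tau_soma(neuron, config)
  list(neuron = neuron, config = config, network = network,
       meanfield = meanfield,
       distance = distance_model(vals$g_max, vals$mu_spatial),
       resolved = vals)
}

.write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_dump <- function(resolved, path) {
  lines <- vapply(names(resolved), function(k) {
    paste0(k, " = ", format(resolved[[k]], scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  path
}

#' Run a named experiment
#'
#' Wires the modules together into reproducible, file-producing
#' experiments. Every run writes the resolved parameters
#' (`<name>_params.cfg`) alongside its result tables (tab-separated text
#' with a header row) in `out_dir`.
#'
#' Available experiments:
#' \describe{
#'   \item{`response-curves`}{on-path somatic response functions `f_d`,
#'     `f_p` over a conductance grid (`responses.tsv`).}
#'   \item{`kappa-scan`}{full-model shunting strength vs the proximal
#'     synaptic conductance for on-path and out-of-path arrangements
#'     (`kappa_scan.tsv`).}
#'   \item{`kappa-distance`}{[kappa_distance_scan()] for inhibitory
#'     anchors 2.2/3/5 nS (`kappa_distance.tsv`).}
#'   \item{`simulate-neuron`}{reduced on-path neuron driven by seeded
#'     Poisson excitation/inhibition (`voltage.tsv`, `spikes.tsv`).}
#'   \item{`simulate-network`}{the spiking network (`raster.tsv`,
#'     `rates.tsv`).}
#'   \item{`meanfield`}{fixed point, stability and optional `w_E` sweep
#'     (`meanfield.tsv`).}
#' }
#'
#' @param name experiment name (see above).
#' @param config_path optional configuration file for [load_config()].
#' @param overrides named list of configuration overrides.
#' @param seed optional seed override.
#' @param out_dir output directory (created if missing).
#' @param duration simulation length in ms for the simulation experiments.
#' @param sweep optional numeric vector of `w_E` values for `meanfield`.
#' @param verbose logical; print one progress line per stage.
#' @return Invisibly, a list with `files` (paths written) and `results`
#'   (the computed objects).
#' @export
run_experiment <- function(name, config_path = NULL, overrides = list(),
                           seed = NULL, out_dir = tempfile("dendshunt_"),
                           duration = 500, sweep = NULL, verbose = FALSE) {
  known <- c("response-curves", "kappa-scan", "kappa-distance",
             "simulate-neuron", "simulate-network", "meanfield")
  if (!name %in% known)
    stop("unknown experiment '", name, "'; available: ",
         paste(known, collapse = ", "))
  if (!is.null(seed)) overrides$seed <- seed
  cfg <- load_config(config_path, overrides)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", name, "] ", ...)
  files <- character(0)
  tag <- gsub("-", "_", name)
  files <- c(files, .write_dump(cfg$resolved,
                                file.path(out_dir, paste0(tag, "_params.cfg"))))
  res <- NULL
  if (name == "response-curves") {
    g <- seq(0, 50, by = 0.5)
    res <- data.frame(g_nS = g,
                      f_d_mV = somatic_response_excitatory(g, cfg$neuron, "on_path"),
                      f_p_mV = somatic_response_inhibitory(g, cfg$neuron, "on_path"))
    files <- c(files, .write_table(res, file.path(out_dir, "responses.tsv")))
  } else if (name == "kappa-scan") {
    say("extracting kappa over the proximal-conductance scan")
    g_scan <- seq(0.5, 20, length.out = 40)
    res <- data.frame(
      g_nS = g_scan,
      kappa_on = vapply(g_scan, function(g)
        extract_shunting_strength(cfg$neuron, g_E = 2, g_I = g, "on_path"),
        numeric(1)),
      kappa_out = vapply(g_scan, function(g)
        extract_shunting_strength(cfg$neuron, g_E = g, g_I = 2, "out_of_path"),
        numeric(1)))
    files <- c(files, .write_table(res, file.path(out_dir, "kappa_scan.tsv")))
  } else if (name == "kappa-distance") {
    anchors <- c(2.2, 3, 5)
    x_E <- seq(2, 120, by = 2)
    res <- kappa_distance_scan(cfg$neuron, anchors, x_E, model = cfg$distance)
    out <- res[, c("x_E", "g_SI_anchor", "kappa")]
    names(out) <- c("x_E", "g_SI_anchor", "kappa")
    files <- c(files, .write_table(out, file.path(out_dir, "kappa_distance.tsv")))
  } else if (name == "simulate-neuron") {
    sd0 <- as.integer(cfg$resolved$seed)
    dt <- cfg$resolved$dt
    trE <- poisson_spike_train(200, duration, seed = sd0)
    trI <- poisson_spike_train(100, duration, seed = sd0 + 1L)
    gE <- evolve_conductance(0, trE, synapse_params(cfg$resolved$tau_E, 2),
                             duration, dt)$g_nS
    gI <- evolve_conductance(0, trI, synapse_params(cfg$resolved$tau_I, 2),
                             duration, dt)$g_nS
    n <- as.integer(round(duration / dt))
    sim <- simulate_reduced_neuron(cfg$neuron, cfg$config,
                                   gE[seq_len(n)], gI[seq_len(n)],
                                   duration, dt,
                                   threshold = cfg$resolved$E_thres,
                                   reset = cfg$resolved$E_reset)
    res <- sim
    files <- c(files,
               .write_table(data.frame(time_ms = sim$trace$time_ms,
                                       v_mV = sim$trace$v_mV),
                            file.path(out_dir, "voltage.tsv")),
               .write_table(data.frame(time_ms = sim$spike_times),
                            file.path(out_dir, "spikes.tsv")))
  } else if (name == "simulate-network") {
    say("simulating ", cfg$network$N_E + cfg$network$N_I, " neurons for ",
        duration, " ms")
    sim <- simulate_network(cfg$network, cfg$neuron, duration)
    rates <- data.frame(
      population = c("E", "I"),
      rate_persistent_Hz = c(
        population_rate(sim, "E", c(max(0, duration - 100), duration)),
        population_rate(sim, "I", c(max(0, duration - 100), duration))),
      rate_spontaneous_Hz = c(
        population_rate(sim, "E", c(0, cfg$network$stim_onset)),
        population_rate(sim, "I", c(0, cfg$network$stim_onset))))
    res <- list(sim = sim, rates = rates)
    files <- c(files,
               .write_table(sim$raster, file.path(out_dir, "raster.tsv")),
               .write_table(rates, file.path(out_dir, "rates.tsv")))
    say("persistent rates: E=", round(rates$rate_persistent_Hz[1], 2),
        " Hz, I=", round(rates$rate_persistent_Hz[2], 2), " Hz")
  } else if (name == "meanfield") {
    w_vals <- if (is.null(sweep)) cfg$meanfield$w_E else sweep
    res <- rate_sweep(cfg$meanfield, w_vals)
    files <- c(files, .write_table(res, file.path(out_dir, "meanfield.tsv")))
  }
  say("wrote ", length(files), " files to ", out_dir)
  invisible(list(files = files, results = res))
}

#' Command-line interface
#'
#' Entry point for the `dendshunt` command-line script (see
#' `system.file("cli", "dendshunt", package = "dendshunt")`). Usage:
#' `dendshunt <experiment> [--config=FILE] [--seed=N] [--out=DIR]
#' [--duration=MS] [--sweep=start:stop:step] [--verbose]` with the
#' experiment names of [run_experiment()].
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status, invisibly: 0 on success, 2 on
#'   configuration errors, 3 on numerical failures.
#' @export
dsh_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: dendshunt <experiment> [--config=FILE] [--seed=N] [--out=DIR]\n",
    "                 [--duration=MS] [--sweep=start:stop:step] [--verbose]\n",
    "experiments: response-curves kappa-scan kappa-distance simulate-neuron\n",
    "             simulate-network meanfield")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  name <- args[1]
  opts <- list(config = NULL, seed = NULL, out = "dendshunt_out",
               duration = 500, sweep = NULL, verbose = FALSE)
  for (a in args[-1]) {
    if (a == "--verbose") { opts$verbose <- TRUE; next }
    m <- regmatches(a, regexec("^--([a-z]+)=(.*)$", a))[[1]]
    if (length(m) != 3L) { message("bad argument: ", a, "\n", usage)
                           return(invisible(2L)) }
    key <- m[2]; val <- m[3]
    if (key == "config") opts$config <- val
    else if (key == "seed") opts$seed <- as.integer(val)
    else if (key == "out") opts$out <- val
    else if (key == "duration") opts$duration <- as.numeric(val)
    else if (key == "sweep") {
      parts <- suppressWarnings(
        as.numeric(strsplit(val, ":", fixed = TRUE)[[1]]))
      if (length(parts) != 3L || any(is.na(parts))) {
        message("bad --sweep (want start:stop:step): ", val)
        return(invisible(2L))
      }
      opts$sweep <- seq(parts[1], parts[2], by = parts[3])
    } else { message("unknown option: --", key, "\n", usage)
             return(invisible(2L)) }
  }
  status <- tryCatch({
    out <- run_experiment(name, config_path = opts$config, seed = opts$seed,
                          out_dir = opts$out, duration = opts$duration,
                          sweep = opts$sweep, verbose = opts$verbose)
    message("wrote: ", paste(out$files, collapse = ", "))
    0L
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("configuration|unknown experiment|malformed|not found", msg))
      2L else 3L
  })
  invisible(status)
}
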