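#' Random irreducible rate-model fixture
#'
#' Property-test input generator: a random connected reversible rate model
#' over `n_states` states with two signal levels realized as two
#' independent random energy landscapes (so the switch does quench work).
#' Rates follow the symmetric local-detailed-balance parameterization with
#' random symmetric attempt scales. If `driven`, a random cycle carries
#' fuel stoichiometry `nu = 1` with a random `dmu` in `[0, 5]`, breaking
#' detailed balance while preserving the affinity decomposition.
#'
#' @param n_states number of states, between 2 and 50.
#' @param driven add a fuel-driven cycle (default `FALSE`).
#' @param seed integer seed; the fixture is reproducible under it.
#' @return list with `model` (a [rate_model()]) and `protocol` (uniform
#'   binary [signal_protocol()]).
#' @export
make_random_model_fixture <- function(n_states, driven = FALSE, seed = 1L) {
  stopifnot(n_states >= 2L, n_states <= 50L)
  set.seed(seed)
  n <- as.integer(n_states)
  energy <- matrix(stats::rnorm(2L * n), n, 2L, dimnames = list(NULL, c("0", "1")))
  # random connected support: spanning tree plus extra edges
  sup <- matrix(FALSE, n, n)
  for (i in seq_len(n)[-1]) {
    j <- sample.int(i - 1L, 1L)
    sup[i, j] <- sup[j, i] <- TRUE
  }
  extra <- which(upper.tri(sup) & !sup & stats::runif(n * n) < 0.3)
  sup[extra] <- TRUE
  sup <- sup | t(sup)
  omega <- matrix(0, n, n)
  omega[sup] <- exp(stats::rnorm(sum(sup), sd = 0.5))
  omega <- (omega + t(omega)) / 2 # symmetric attempt rates
  nu <- matrix(0L, n, n)
  dmu <- 0
  if (driven && n >= 3L) {
    len <- sample(3:min(n, 6L), 1L)
    cyc <- sample.int(n, len)
    for (q in seq_len(len)) {
      i <- cyc[q]
      j <- cyc[if (q == len) 1L else q + 1L]
      sup[i, j] <- sup[j, i] <- TRUE
      if (omega[i, j] == 0) omega[i, j] <- omega[j, i] <- exp(stats::rnorm(1, sd = 0.5))
      nu[j, i] <- nu[j, i] + 1L # consume one fuel on i -> j
      nu[i, j] <- nu[i, j] - 1L
    }
    dmu <- stats::runif(1, 0, 5)
  }
  W <- lapply(c(1L, 2L), function(s) {
    e <- energy[, s]
    w <- matrix(0, n, n)
    idx <- which(sup, arr.ind = TRUE)
    w[idx] <- omega[idx] *
      exp((-(e[idx[, 1]] - e[idx[, 2]]) + dmu * nu[idx]) / 2)
    w
  })
  names(W) <- c("0", "1")
  model <- rate_model(state_space(data.frame(x = seq_len(n) - 1L)), W,
                      energy = energy, nu = nu, dmu = dmu)
  list(model = model, protocol = signal_protocol(c(0, 1)))
}

.experiments <- c("feedforward_info", "feedforward_thermo",
                  "chemotaxis_step", "chemotaxis_tradeoff", "custom_model")

.config_schema <- list(
  top = c("experiment", "seed", "units", "model", "time_grid", "protocol",
          "output_dir", "sweep", "model_file"),
  model_feedforward = c("eps_a", "eps_m", "eps_g", "abar", "omega_a", "omega_m"),
  model_chemotaxis = c("eps_r_kT", "m0", "K_I_uM", "K_A_uM", "dmu_kT",
                       "omega_a", "omega_m", "L0_uM", "L1_uM", "readapt_tol"),
  time_grid = c("t_min", "t_max", "n", "spacing"),
  protocol = c("prior", "kernel"),
  sweep = c("L1_min_uM", "L1_max_uM", "n")
)

#' Validate an experiment configuration
#'
#' Schema check: the experiment name must be one of
#' `feedforward_info`, `feedforward_thermo`, `chemotaxis_step`,
#' `chemotaxis_tradeoff`, `custom_model`; unknown keys anywhere are
#' rejected with a list of the offending names.
#'
#' @param config named list (e.g. from [read_experiment_config()]).
#' @return the config, invisibly, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.null(config$experiment) || !config$experiment %in% .experiments) {
    stop(sprintf(
      "config must name an experiment among: %s",
      paste(.experiments, collapse = ", ")
    ))
  }
  .reject_unknown(config, .config_schema$top, "top level")
  model_keys <- if (startsWith(config$experiment, "feedforward")) {
    .config_schema$model_feedforward
  } else {
    .config_schema$model_chemotaxis
  }
  if (!is.null(config$model)) .reject_unknown(config$model, model_keys, "model block")
  if (!is.null(config$time_grid)) {
    .reject_unknown(config$time_grid, .config_schema$time_grid, "time_grid block")
  }
  if (!is.null(config$protocol)) {
    .reject_unknown(config$protocol, .config_schema$protocol, "protocol block")
  }
  if (!is.null(config$sweep)) {
    .reject_unknown(config$sweep, .config_schema$sweep, "sweep block")
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$units)) config$units <- "bits"
  if (!config$units %in% c("bits", "nats")) stop("units must be 'bits' or 'nats'")
  invisible(config)
}

.reject_unknown <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop(sprintf(
      "unknown %s config keys: %s (allowed: %s)",
      where, paste(unknown, collapse = ", "), paste(allowed, collapse = ", ")
    ))
  }
}

#' Read an experiment configuration file (JSON)
#' @param path JSON file path.
#' @return validated config list.
#' @export
read_experiment_config <- function(path) {
  validate_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

.config_times <- function(config, model) {
  tg <- config$time_grid
  if (is.null(tg)) return(default_time_grid(model))
  n <- if (is.null(tg$n)) 240 else tg$n
  spacing <- if (is.null(tg$spacing)) "log" else tg$spacing
  if (is.null(tg$t_min) || is.null(tg$t_max)) {
    default_time_grid(model, n = n)
  } else {
    times_grid(tg$t_min, tg$t_max, n = n, spacing = spacing)
  }
}

.config_feedforward_params <- function(config) {
  m <- config$model
  if (is.null(m)) m <- list()
  pr <- config$protocol
  do.call(feedforward_params, c(
    m,
    if (!is.null(pr$prior)) list(prior = pr$prior),
    if (!is.null(pr$kernel)) list(kernel = matrix(unlist(pr$kernel), 2, 2, byrow = TRUE))
  ))
}

.config_chemotaxis_params <- function(config) {
  m <- config$model
  if (is.null(m)) m <- list()
  args <- list(
    eps_r = m$eps_r_kT, m0 = m$m0, K_I = m$K_I_uM, K_A = m$K_A_uM,
    dmu = m$dmu_kT, omega_a = m$omega_a, omega_m = m$omega_m,
    readapt_tol = m$readapt_tol
  )
  do.call(chemotaxis_params, args[!vapply(args, is.null, logical(1))])
}

# stable content hash (31-polynomial mod 2^31) of the canonical config JSON
.config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run a configured experiment
#'
#' Dispatches to the bundled model drivers, optionally writes tidy CSV
#' ledgers and a JSON summary (with config hash, seed and package version
#' as provenance), and returns the result bundle. All bundled experiments
#' are deterministic linear-algebra computations: the same config yields
#' identical numbers.
#'
#' @param config a validated config list or a path to a JSON config file.
#' @param output_dir overrides `config$output_dir`; `NULL` skips writing.
#' @return list with `config`, experiment results (ledgers in the
#'   requested units), `bounds` where applicable, and `provenance`.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  config <- validate_config(config)
  set.seed(config$seed)
  if (is.null(output_dir)) output_dir <- config$output_dir
  conv <- if (config$units == "bits") to_bits else identity
  name <- config$experiment
  res <- switch(name,
    feedforward_info = ,
    feedforward_thermo = {
      params <- .config_feedforward_params(config)
      model <- build_rates(params)
      run <- run_feedforward_protocol(params, times = .config_times(config, model))
      list(info = conv(run$info), thermo = conv(run$thermo), bounds = run$bounds)
    },
    chemotaxis_step = {
      params <- .config_chemotaxis_params(config)
      m <- config$model
      L0 <- if (is.null(m$L0_uM)) 94 else m$L0_uM
      L1 <- if (is.null(m$L1_uM)) 720 else m$L1_uM
      gen <- build_chemotaxis_generator(params, c(L0, L1))
      run <- run_chemotaxis_step(params, L0, L1,
                                 times = .config_times(config, gen))
      list(info = conv(run$info), thermo = conv(run$thermo),
           bounds = run$bounds, summary = run$summary)
    },
    chemotaxis_tradeoff = {
      params <- .config_chemotaxis_params(config)
      m <- config$model
      L0 <- if (is.null(m$L0_uM)) 94 else m$L0_uM
      sw <- config$sweep
      grid <- if (is.null(sw)) NULL else {
        exp(seq(log(sw$L1_min_uM), log(sw$L1_max_uM), length.out = sw$n))
      }
      list(sweep = sweep_tradeoff(params, L0, grid))
    },
    custom_model = {
      if (is.null(config$model_file)) stop("custom_model needs a model_file")
      model <- model_from_json(config$model_file)
      pr <- config$protocol
      protocol <- signal_protocol(
        model$signals,
        prior = pr$prior,
        kernel = if (is.null(pr$kernel)) NULL else
          matrix(unlist(pr$kernel), length(model$signals), byrow = TRUE)
      )
      traj <- ensemble_propagate(model, protocol, .config_times(config, model))
      info <- information_decomposition(traj, NULL, NULL)
      thermo <- thermo_ledger(traj)
      list(info = conv(info), thermo = conv(thermo),
           bounds = check_information_bounds(info, thermo))
    }
  )
  provenance <- list(
    experiment = name, seed = config$seed, units = config$units,
    config_hash = .config_hash(config),
    package_version = as.character(utils::packageVersion("sensotherm"))
  )
  bundle <- c(list(config = config), res, list(provenance = provenance))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in intersect(c("info", "thermo", "sweep"), names(res))) {
      write_timeseries(res[[nm]], file.path(output_dir, paste0(name, "_", nm, ".csv")))
    }
    summary <- list(provenance = provenance)
    if (!is.null(res$summary)) summary$cost_summary <- res$summary
    if (!is.null(res$bounds)) {
      summary$bound_margins <- stats::setNames(
        as.list(res$bounds$margin_min), res$bounds$bound
      )
    }
    jsonlite::write_json(summary, file.path(output_dir, paste0(name, "_summary.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Write a ledger as a tidy CSV
#'
#' Long format with columns `time` (or the sweep key), `quantity`,
#' `value`, `units`; values are printed with 17 significant digits so a
#' read round-trips to the exact doubles.
#'
#' @param ledger a ledger data.frame (wide).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(ledger, path) {
  df <- as.data.frame(ledger)
  units <- attr(ledger, "units")
  if (is.null(units)) units <- "nats"
  key <- if ("time" %in% names(df)) "time" else names(df)[1]
  qcols <- setdiff(names(df), key)
  info_cols <- .info_unit_cols
  nr <- nrow(df)
  rows <- lapply(qcols, function(q) {
    data.frame(
      key = df[[key]], quantity = rep(q, nr), value = df[[q]],
      units = rep(if (q %in% info_cols) units else "kT", nr),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- key
  out[[key]] <- sprintf("%.17g", out[[key]])
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a tidy ledger CSV into wide form
#' @param path CSV written by [write_timeseries()].
#' @return wide data.frame with a `units` attribute.
#' @export
read_timeseries <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- names(long)[1]
  long[[key]] <- as.numeric(long[[key]])
  long$value <- as.numeric(long$value)
  qs <- unique(long$quantity)
  keys <- unique(long[[key]])
  wide <- data.frame(key = keys)
  names(wide) <- key
  for (q in qs) {
    sub <- long[long$quantity == q, ]
    wide[[q]] <- sub$value[match(keys, sub[[key]])]
  }
  iu <- unique(long$units[long$quantity %in% .info_unit_cols])
  attr(wide, "units") <- if (length(iu) == 1) iu else "nats"
  wide
}

#' Command-line entry point
#'
#' Implements `sensotherm run <config.json> [--check]`,
#' `sensotherm list-experiments`, and
#' `sensotherm fixtures --n <k> --seed <s> --out <dir>`. In `--check`
#' mode the exit status is nonzero if any information bound is violated
#' beyond tolerance.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 ok), invisibly.
#' @export
sensotherm_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: sensotherm run <config.json> [--out <dir>] [--check]",
    "       sensotherm list-experiments",
    "       sensotherm fixtures --n <k> [--states <n>] [--seed <s>] [--out <dir>]",
    sep = "\n"
  )
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (!length(i)) return(default)
    rest[i[1] + 1L]
  }
  status <- 0L
  if (cmd == "list-experiments") {
    cat(paste(.experiments, collapse = "\n"), "\n")
  } else if (cmd == "run") {
    cfg_path <- rest[!startsWith(rest, "--")][1]
    if (is.na(cfg_path)) stop(usage)
    t0 <- proc.time()[["elapsed"]]
    bundle <- run_experiment(cfg_path, output_dir = opt("--out"))
    message(sprintf("[sensotherm] %s done in %.2fs (config %s)",
                    bundle$provenance$experiment,
                    proc.time()[["elapsed"]] - t0,
                    bundle$provenance$config_hash))
    if ("--check" %in% rest && !is.null(bundle$bounds) &&
        !all(bundle$bounds$holds)) {
      message("[sensotherm] BOUND VIOLATION:")
      message(paste(utils::capture.output(print(
        bundle$bounds[!bundle$bounds$holds, ])), collapse = "\n"))
      status <- 2L
    }
  } else if (cmd == "fixtures") {
    k <- as.integer(opt("--n", "10"))
    n_states <- as.integer(opt("--states", "5"))
    seed <- as.integer(opt("--seed", "1"))
    out <- opt("--out", ".")
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (q in seq_len(k)) {
      fx <- make_random_model_fixture(n_states, driven = q %% 2L == 0L,
                                      seed = seed + q)
      model_to_json(fx$model, file.path(out, sprintf("fixture_%03d.json", q)))
    }
    message(sprintf("[sensotherm] wrote %d fixtures to %s", k, out))
  } else {
    message(usage)
    status <- 1L
  }
  invisible(status)
}
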