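# Archive reading/writing, run configuration, and the command-line entry
# point. Archives are one directory per run: per-step samples as
# tab-separated text (time_ns, z_angstrom) and a JSON metadata document.
# Samples are canonical; histograms, mean positions and work increments
# are recomputed on read.

fmt_num <- function(x) sprintf("%.17g", x)

potential_to_list <- function(pot) {
  list(form = pot$form, type_code = pot$type_code, par = pot$par,
       domain = pot$domain, label = pot$label)
}

potential_from_list <- function(pl) {
  par <- pl$par
  if (pl$type_code == 4) par$coefs <- as.matrix(par$coefs)
  for (nm in names(par)) {
    if (is.list(par[[nm]])) par[[nm]] <- unlist(par[[nm]])
  }
  structure(list(form = pl$form, type_code = as.integer(pl$type_code),
                 par = par, domain = unlist(pl$domain), label = pl$label),
            class = "potential1d")
}

#' Hash of a configuration object
#'
#' Canonical-JSON MD5 used to stamp outputs and to verify that an archive
#' matches its declared configuration.
#'
#' @param x Any JSON-serialisable object.
#' @return MD5 hex string.
#' @export
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

archive_meta <- function(run) {
  list(
    format = "ionpull_archive_v1",
    schedule = unclass(run$schedule),
    params = unclass(run$params)[c("temperature", "diffusion", "timestep",
                                   "sample_interval")],
    master_seed = run$master_seed,
    potential = potential_to_list(run$potential),
    bin_width = run$bin_width,
    steps = lapply(run$steps, function(st) {
      list(index = st$index, lambda = st$lambda, z_init = fmt_num(st$z_init),
           z_after_tau1 = fmt_num(st$z_after_tau1))
    })
  )
}

#' Write a pulling-run archive to a directory
#'
#' @param run A `pulling_run`.
#' @param dir Output directory (created; must not already contain an
#'   archive).
#' @return Invisibly, `dir`.
#' @export
write_pulling_run <- function(run, dir) {
  stopifnot(inherits(run, "pulling_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- archive_meta(run)
  meta$config_hash <- config_hash(meta)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (st in run$steps) {
    df <- data.frame(time_ns = fmt_num(st$samples$time),
                     z_angstrom = fmt_num(st$samples$z))
    write.table(df, file.path(dir, sprintf("step_%03d.tsv", st$index)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a pulling-run archive from a directory
#'
#' Samples are canonical: histograms, mean positions and work increments
#' are recomputed. The stored configuration hash is verified.
#'
#' @param dir Archive directory.
#' @return A `pulling_run`.
#' @export
read_pulling_run <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  if (is.null(meta$format) || meta$format != "ionpull_archive_v1") {
    stop("not an ionpull archive: ", dir)
  }
  stored_hash <- meta$config_hash
  meta$config_hash <- NULL
  if (!identical(unname(config_hash(meta)), unname(unlist(stored_hash)))) {
    stop("archive metadata hash mismatch in ", dir)
  }
  sc <- meta$schedule
  schedule <- pulling_schedule(sc$lambda_start, sc$delta_lambda, sc$n_steps,
                               sc$tau1, sc$tau2, sc$k, sc$direction)
  pr <- meta$params
  params <- langevin_params(pr$temperature, pr$diffusion, pr$timestep,
                            seed = meta$master_seed, sample_interval = pr$sample_interval)
  potential <- potential_from_list(meta$potential)
  lam <- lambda_grid(schedule)
  dl <- signed_delta_lambda(schedule)
  bw <- meta$bin_width
  steps <- vector("list", schedule$n_steps)
  for (i in seq_len(schedule$n_steps)) {
    m <- meta$steps[[i]]
    tsv <- read.table(file.path(dir, sprintf("step_%03d.tsv", i - 1L)),
                      header = TRUE, sep = "\t",
                      colClasses = c("numeric", "numeric"))
    samples <- data.frame(time = tsv$time_ns, z = tsv$z_angstrom)
    steps[[i]] <- list(
      index = i - 1L, lambda = lam[i], samples = samples,
      z_init = as.numeric(m$z_init),
      z_after_tau1 = as.numeric(m$z_after_tau1),
      mean_z = mean(samples$z),
      g = step_density(samples$z, bw),
      work_increments = step_work_increment(samples$z, lam[i], dl,
                                            schedule$k)
    )
  }
  structure(list(schedule = schedule, params = params,
                 master_seed = meta$master_seed, potential = potential,
                 potential_label = potential$label, steps = steps,
                 bin_width = bw),
            class = "pulling_run")
}

#' Write / read a free-energy profile
#'
#' Tab-separated `(lambda_angstrom, delta_F_kcalmol, se)` with a JSON
#' sidecar (`<path>.json`) holding estimator and temperature; the
#' round-trip is lossless.
#'
#' @param profile A `free_energy_profile`.
#' @param path Output TSV path.
#' @return Invisibly `path` (write) or the profile (read).
#' @export
write_fe_profile <- function(profile, path) {
  df <- data.frame(lambda_angstrom = fmt_num(profile$lambda),
                   delta_F_kcalmol = fmt_num(profile$delta_F),
                   se = fmt_num(profile$se))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(estimator = attr(profile, "estimator"),
                            temperature = attr(profile, "temperature")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fe_profile
#' @export
read_fe_profile <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "numeric")
  meta <- jsonlite::read_json(paste0(path, ".json"))
  new_fe_profile(df$lambda_angstrom, df$delta_F_kcalmol, df$se,
                 meta$estimator,
                 if (is.null(meta$temperature)) NA_real_
                 else as.numeric(meta$temperature))
}

# ---------------------------------------------------------------------------
# Run configuration and CLI

config_potential <- function(cfg) {
  if (!is.null(cfg$species)) return(make_species_fixture(cfg$species))
  p <- cfg$potential
  if (is.null(p)) stop("config must give either `species` or `potential`")
  switch(p$form,
    harmonic = potential_harmonic(p$a, p$center %||% 0),
    double_well = potential_double_well(p$height, p$center %||% 0,
                                        p$half_width %||% 1),
    piecewise_multiwell = potential_multiwell(unlist(p$centers),
                                              unlist(p$depths),
                                              unlist(p$widths %||% 0.5),
                                              p$zlo %||% 0, p$zhi %||% 25,
                                              p$k_wall %||% 10),
    tabulated = potential_tabulated(unlist(p$z), unlist(p$energy)),
    stop("unknown potential form: ", p$form)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a simulation from a configuration list or JSON file
#'
#' The configuration holds the potential (a `species` fixture name or an
#' explicit potential spec), the schedule, engine parameters, and the
#' master seed; re-running from the saved configuration reproduces the
#' archive bit-for-bit.
#'
#' @param config A list, or path to a JSON file.
#' @param out Output archive directory (overrides `config$out`).
#' @return The `pulling_run`, invisibly, after writing the archive.
#' @export
cli_simulate <- function(config, out = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  out <- out %||% config$out
  if (is.null(out)) stop("no output directory given")
  sc <- config$schedule %||% list()
  schedule <- pulling_schedule(
    sc$lambda_start %||% 0, sc$delta_lambda %||% 1.0, sc$n_steps %||% 25,
    sc$tau1 %||% 0.5, sc$tau2 %||% 10, sc$k %||% 0.6,
    sc$direction %||% "forward")
  en <- config$engine %||% list()
  params <- langevin_params(en$temperature %||% 310, en$diffusion %||% 0.5,
                            en$timestep %||% 1e-4,
                            seed = config$seed %||% 1,
                            sample_interval = en$sample_interval %||% 1e-4)
  potential <- config_potential(config)
  run <- run_stepwise_pulling(potential, schedule, params,
                              z0 = config$z0 %||% NULL)
  write_pulling_run(run, out)
  message("archive written to ", out, " (", schedule$n_steps, " steps)")
  invisible(run)
}

#' Analyse one or two archives and write report files
#'
#' Writes free-energy profiles (both estimators), and optionally the
#' stable-state table, the conductance profile, a convergence trace, and
#' (with two archives) the profile difference and selectivity ratio. A
#' `summary.json` carries the archive hashes and headline numbers.
#'
#' @param archive Archive directory (species A).
#' @param out Output directory.
#' @param archive2 Optional second archive (species B) for differences.
#' @param temperature Analysis temperature, Kelvin.
#' @param states,conductance Logical switches for the optional reports.
#' @param convergence Optional lambda (Angstrom) for a convergence trace.
#' @param n_draws Monte-Carlo draws for the Jarzynski assembly.
#' @param seed Analysis seed.
#' @return Invisibly, the summary list.
#' @export
cli_analyze <- function(archive, out, archive2 = NULL, temperature = 310,
                        states = FALSE, conductance = FALSE,
                        convergence = NULL, n_draws = 1e4, seed = 1) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  runA <- read_pulling_run(archive)
  validate_pulling_run(runA)
  summary <- list(archive = archive,
                  archive_hash = jsonlite::read_json(
                    file.path(archive, "meta.json"))$config_hash)
  qeA <- quasi_equilibrium_delta_f(runA, temperature, n_boot = 50,
                                   seed = seed)
  wsA <- assemble_work_distribution(runA, n_draws = n_draws, seed = seed)
  jzA <- jarzynski_delta_f(wsA, temperature, n_boot = 50, seed = seed)
  write_fe_profile(qeA, file.path(out, "fe_quasi_A.tsv"))
  write_fe_profile(jzA, file.path(out, "fe_jarzynski_A.tsv"))
  if (!is.null(archive2)) {
    runB <- read_pulling_run(archive2)
    validate_pulling_run(runB)
    if (max(abs(lambda_grid(runA$schedule) -
                lambda_grid(runB$schedule))) > 1e-9) {
      stop("lambda grids of the two archives do not match")
    }
    qeB <- quasi_equilibrium_delta_f(runB, temperature, n_boot = 50,
                                     seed = seed)
    write_fe_profile(qeB, file.path(out, "fe_quasi_B.tsv"))
    dd <- delta_delta_f(qeA, qeB)
    write.table(data.frame(lambda_angstrom = fmt_num(dd$lambda),
                           ddF_kcalmol = fmt_num(dd$delta_delta_F)),
                file.path(out, "ddf.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    summary$ddf_peak_lambda <- dd$peak_lambda
    summary$ddf_peak_value <- dd$peak_value
    summary$selectivity_ratio <- selectivity_ratio(dd$peak_value,
                                                   temperature)
  }
  if (states) {
    pool <- pooled_samples(runA)
    zfit <- if (nrow(pool) > 5e4) pool$z[seq(1, nrow(pool),
                                             length.out = 5e4)] else pool$z
    mix <- fit_position_mixture(zfit, max_components = 6)
    write.table(format(as.data.frame(mix), digits = 6),
                file.path(out, "states_A.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    segs <- partition_forces(runA, mix)
    if (length(segs) >= 2) {
      tp <- vapply(seq_len(length(segs) - 1), function(i) {
        transition_probability(segs[[i]], segs[[i + 1]])
      }, 1)
      write.table(data.frame(from_z = vapply(segs[-length(segs)],
                                             `[[`, 1, "mean_z"),
                             to_z = vapply(segs[-1], `[[`, 1, "mean_z"),
                             probability = tp),
                  file.path(out, "transitions_A.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    summary$n_states <- nrow(mix)
  }
  if (conductance) {
    prof <- conductance_profile(runA, n_pairs = 2000, seed = seed)
    lamA <- lambda_grid(runA$schedule)
    write.table(data.frame(
      lambda_pair = sprintf("%g-%g", lamA[-length(lamA)], lamA[-1]),
      G_pS = vapply(prof, `[[`, 1, "G_pS"),
      mean_work_kcalmol = vapply(prof, `[[`, 1, "mean_work"),
      dispersion_A2_per_ns = vapply(prof, `[[`, 1, "dispersion")),
      file.path(out, "conductance_A.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    tot <- total_conductance(prof)
    summary$G_total_pS <- tot$G_total_pS
    summary$W_total_kcalmol <- tot$W_total
  }
  if (!is.null(convergence)) {
    taus <- seq(runA$schedule$tau2 / 5, runA$schedule$tau2, length.out = 5)
    tr <- convergence_trace(runA, convergence, taus, temperature)
    write.table(data.frame(tau_ns = tr$tau, value_kcalmol = tr$value),
                file.path(out, "convergence_A.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$converged <- attr(tr, "converged")
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

parse_cli_args <- function(args) {
  opts <- list(positional = character(0))
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]; i <- i + 2
      } else {
        opts[[key]] <- TRUE; i <- i + 1
      }
    } else {
      opts$positional <- c(opts$positional, a); i <- i + 1
    }
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `simulate --config FILE [--out DIR]`,
#' `analyze --archive DIR --out DIR [--archive2 DIR] [--states]
#' [--conductance] [--convergence LAMBDA] [--seed N]`,
#' `fixtures --out DIR` (writes ready-to-run K-like/Na-like configs).
#' Exit codes: 0 ok, 1 user error, 2 internal inconsistency.
#'
#' @param args Character vector of command-line arguments.
#' @return The exit status, invisibly.
#' @export
ionpull_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop("usage: ionpull <simulate|analyze|fixtures> ...")
    cmd <- args[1]
    opts <- parse_cli_args(args[-1])
    if (cmd == "simulate") {
      if (is.null(opts$config)) stop("simulate requires --config")
      cli_simulate(opts$config, out = opts$out)
    } else if (cmd == "analyze") {
      if (is.null(opts$archive) || is.null(opts$out)) {
        stop("analyze requires --archive and --out")
      }
      cli_analyze(opts$archive, opts$out, archive2 = opts$archive2,
                  temperature = as.numeric(opts$temperature %||% 310),
                  states = isTRUE(opts$states),
                  conductance = isTRUE(opts$conductance),
                  convergence = if (is.null(opts$convergence)) NULL
                                else as.numeric(opts$convergence),
                  seed = as.integer(opts$seed %||% 1))
    } else if (cmd == "fixtures") {
      out <- opts$out %||% "."
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      for (sp in c("K_like", "Na_like")) {
        cfg <- list(species = sp,
                    schedule = list(n_steps = 25, tau1 = 0.5, tau2 = 1),
                    engine = list(temperature = 310, diffusion = 0.5),
                    seed = if (sp == "K_like") 11 else 12,
                    out = file.path(out, paste0("archive_", sp)))
        jsonlite::write_json(cfg, file.path(out, paste0(sp, ".json")),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
      message("fixture configs written to ", out)
    } else {
      stop("unknown subcommand: ", cmd)
    }
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("internal inconsistency", conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}
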