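#' Write and read the canonical long-format trace family
#'
#' The canonical on-disk representation of a current family is a long CSV
#' with one row per sample: columns `family_id`, `trace_id`, `V_test_mV`,
#' `V_hold_mV`, `V_repol_mV`, `step_dur_s`, `pH_o`, `pH_i`, `C_m_pF`, `t_s`,
#' `I_pA`. An equivalent JSON representation nests the same fields per
#' trace. Round trips are lossless up to numeric printing precision.
#'
#' @param family a `"trace_family"`.
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @param family_id identifier written to the file.
#' @return `write_trace_family()` returns `path` invisibly;
#'   [read_trace_family()] returns a `"trace_family"`.
#' @export
write_trace_family <- function(family, path, family_id = "family1") {
  stopifnot(inherits(family, "trace_family"))
  rows <- do.call(rbind, lapply(seq_along(family$traces), function(i) {
    tr <- family$traces[[i]]
    data.frame(family_id = family_id, trace_id = i,
               V_test_mV = tr$V_test, V_hold_mV = tr$V_hold,
               V_repol_mV = tr$V_repol, step_dur_s = tr$step_dur,
               pH_o = tr$pH_o, pH_i = tr$pH_i, C_m_pF = tr$C_m,
               t_s = tr$t, I_pA = tr$I)
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    traces <- lapply(seq_along(family$traces), function(i) {
      tr <- family$traces[[i]]
      list(trace_id = i, V_test_mV = tr$V_test, V_hold_mV = tr$V_hold,
           V_repol_mV = tr$V_repol, step_dur_s = tr$step_dur,
           pH_o = tr$pH_o, pH_i = tr$pH_i, C_m_pF = tr$C_m,
           t_s = tr$t, I_pA = tr$I)
    })
    jsonlite::write_json(list(family_id = family_id, traces = traces),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

.TRACE_COLUMNS <- c("family_id", "trace_id", "V_test_mV", "V_hold_mV",
                    "V_repol_mV", "step_dur_s", "pH_o", "pH_i", "C_m_pF",
                    "t_s", "I_pA")

#' @rdname write_trace_family
#' @export
read_trace_family <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    trs <- obj$traces
    if (is.data.frame(trs)) trs <- split(trs, seq_len(nrow(trs)))
    traces <- lapply(trs, function(tr) {
      structure(list(t = unlist(tr$t_s), I = unlist(tr$I_pA),
                     V_test = tr$V_test_mV[[1]], V_hold = tr$V_hold_mV[[1]],
                     V_repol = tr$V_repol_mV[[1]], step_dur = tr$step_dur_s[[1]],
                     tail_dur = max(unlist(tr$t_s)) - tr$step_dur_s[[1]],
                     pH_o = tr$pH_o[[1]], pH_i = tr$pH_i[[1]],
                     C_m = tr$C_m_pF[[1]],
                     label = sprintf("step_%+d_mV", round(tr$V_test_mV[[1]]))),
                class = "current_trace")
    })
  } else {
    d <- utils::read.csv(path)
    missing_cols <- setdiff(.TRACE_COLUMNS, names(d))
    if (length(missing_cols) > 0) {
      stop("trace file schema violation: missing column(s) ",
           paste(missing_cols, collapse = ", "))
    }
    if (nrow(d) == 0) {
      warning("empty trace family file")
      return(structure(list(traces = list(), protocol = NULL,
                            pH_o = NA, pH_i = NA,
                            T_K = hv1_default_temperature(), C_m = NA),
                       class = "trace_family"))
    }
    traces <- lapply(split(d, d$trace_id), function(tr) {
      structure(list(t = tr$t_s, I = tr$I_pA,
                     V_test = tr$V_test_mV[1], V_hold = tr$V_hold_mV[1],
                     V_repol = tr$V_repol_mV[1], step_dur = tr$step_dur_s[1],
                     tail_dur = max(tr$t_s) - tr$step_dur_s[1],
                     pH_o = tr$pH_o[1], pH_i = tr$pH_i[1], C_m = tr$C_m_pF[1],
                     label = sprintf("step_%+d_mV", round(tr$V_test_mV[1]))),
                class = "current_trace")
    })
  }
  names(traces) <- NULL
  if (length(traces) == 0) warning("empty trace family")
  first <- if (length(traces) > 0) traces[[1]] else
    list(pH_o = NA, pH_i = NA, C_m = NA)
  structure(list(traces = traces, protocol = NULL,
                 pH_o = first$pH_o, pH_i = first$pH_i,
                 T_K = hv1_default_temperature(), C_m = first$C_m),
            class = "trace_family")
}

#' Write or read a mutation table as CSV
#'
#' @param records mutation data frame (see [generate_mutation_table()]).
#' @param path CSV file path.
#' @return `read_mutation_table()` returns the validated data frame.
#' @export
write_mutation_table <- function(records, path) {
  validate_mutations(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutation_table
#' @export
read_mutation_table <- function(path) {
  d <- utils::read.csv(path)
  need <- c("position", "ref_aa", "alt_aa")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop("mutation file schema violation: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  validate_mutations(d)
  d
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration with per-module sections and applies
#' defaults. Unknown top-level keys are rejected to catch typos early.
#'
#' @param path YAML/JSON file, or `NULL` for pure defaults.
#' @return A named list of class `"hv1_config"`.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    temperature_K = hv1_default_temperature(),
    seed = 1,
    params = list(),          # channel_params overrides
    protocol = list(),        # voltage_protocol overrides
    gating = list(k_sd = 3),
    leak = list(k_sd = 3, window_s = 10, guard_s = 0.5),
    hotspot = list(window = 7, threshold_factor = 2),
    structure = list(d_on = 4.0, s_hi = 0.65, s_lo = 0.25,
                     radius = 8, bin_width = 1))
  if (is.null(path)) {
    cfg <- defaults
  } else {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg <- utils::modifyList(defaults, user)
  }
  structure(cfg, class = "hv1_config")
}

#' Run a pipeline stage from a configuration
#'
#' Dispatcher behind the command-line wrapper (`inst/exec/hv1`). Each
#' subcommand reads its inputs, runs the corresponding package functions
#' deterministically under the configured seed, writes its artifacts under
#' `out_dir`, and returns the result invisibly. Parameters are echoed to a
#' structured log connection.
#'
#' @param subcommand one of `"simulate-family"`, `"simulate-mutations"`,
#'   `"fit"`, `"gating"`, `"hotspot"`.
#' @param config an `"hv1_config"` (see [load_config()]) or a path.
#' @param input input file for analysis subcommands (trace or mutation
#'   file).
#' @param out_dir output directory (created if needed).
#' @param seed overrides the configured seed.
#' @param log_con connection for the structured log (default `stderr()`).
#' @return The stage result, invisibly.
#' @export
hv1_run <- function(subcommand, config = NULL, input = NULL,
                    out_dir = ".", seed = NULL, log_con = stderr()) {
  if (is.character(config) || is.null(config)) config <- load_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logmsg <- function(...) cat(sprintf(...), "\n", file = log_con)
  logmsg("hv1kit %s | subcommand=%s seed=%s T=%g K",
         as.character(utils::packageVersion("hv1kit")), subcommand,
         config$seed, config$temperature_K)

  result <- switch(
    subcommand,
    "simulate-family" = {
      params <- do.call(channel_params,
                        utils::modifyList(list(seed = config$seed),
                                          config$params))
      protocol <- do.call(voltage_protocol, config$protocol)
      fam <- simulate_family(params, protocol)
      out <- file.path(out_dir, "family.csv")
      write_trace_family(fam, out)
      logmsg("wrote %d traces to %s", length(fam$traces), out)
      fam
    },
    "simulate-mutations" = {
      tab <- generate_mutation_table(length = 273, seed = config$seed,
                                     hotspots = data.frame(
                                       center = c(60, 210),
                                       halfwidth = c(20, 15),
                                       n_mut = c(40, 35)))
      out <- file.path(out_dir, "mutations.csv")
      write_mutation_table(tab, out)
      logmsg("wrote %d mutation records to %s", nrow(tab), out)
      tab
    },
    "fit" = ,
    "gating" = {
      if (is.null(input)) stop("subcommand '", subcommand, "' requires an input trace file")
      fam <- read_trace_family(input)
      fit <- fit_channel(fam, k_sd = config$gating$k_sd,
                         T_K = config$temperature_K)
      out <- file.path(out_dir, "gating_summary.csv")
      utils::write.csv(data.frame(parameter = names(coef(fit)),
                                  value = unname(coef(fit))),
                       out, row.names = FALSE)
      logmsg("wrote gating summary to %s", out)
      fit
    },
    "hotspot" = {
      if (is.null(input)) stop("subcommand 'hotspot' requires a mutation CSV")
      tab <- read_mutation_table(input)
      prof <- window_scan(tab, protein_length = max(tab$position),
                          window = config$hotspot$window)
      out <- file.path(out_dir, "window_profile.csv")
      utils::write.csv(as.data.frame(prof), out, row.names = FALSE)
      calls <- hotspot_calls(prof, config$hotspot$threshold_factor)
      utils::write.csv(calls, file.path(out_dir, "hotspot_calls.csv"),
                       row.names = FALSE)
      logmsg("wrote window profile (%d residues, %d hotspot call(s))",
             nrow(prof), nrow(calls))
      prof
    },
    stop("unknown subcommand: ", subcommand))
  invisible(result)
}
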