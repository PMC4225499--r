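# Sweep-table serialization and reproducible pipeline runs.
#
# A sweep set is stored as one delimited text file (column 1: time in ms,
# one column per sweep, header row of sweep labels; P/4 subsweeps as extra
# labelled columns) plus a JSON sidecar (<path>.meta.json) holding the
# protocol, solutions, conditions and seed. Values round-trip at full float
# precision.

#' Write a sweep set to a sweep-table file with JSON sidecar
#'
#' @param sweeps A `sweep_set`.
#' @param path Output file (tab-delimited text); the sidecar goes to
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_sweepset <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  m <- cbind(time_ms = sweeps$time_ms, sweeps$current_pA)
  if (!is.null(sweeps$subsweeps)) {
    for (s in seq_along(sweeps$subsweeps)) {
      sub <- sweeps$subsweeps[[s]]
      colnames(sub) <- sprintf("sw%02d_p4_%d", s, seq_len(ncol(sub)))
      m <- cbind(m, sub)
    }
  }
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(paste(colnames(m), collapse = "\t"), txt), path)
  meta <- list(
    format = "bacnav-sweep-table", version = 1,
    channel_name = sweeps$channel_name,
    protocol = unclass(sweeps$protocol),
    internal = solution_meta(sweeps$internal),
    external = solution_meta(sweeps$external),
    conditions = unclass(sweeps$conditions),
    drug = sweeps$drug,
    p4_subtracted = sweeps$p4_subtracted
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# named atomic vectors lose their names in JSON; carry components as a map
solution_meta <- function(sol) {
  if (is.null(sol)) return(NULL)
  list(components = as.list(sol$components), pH = sol$pH, ljp = sol$ljp,
       titrant = sol$titrant)
}

# rebuild a solution_composition from its sidecar representation
rebuild_solution <- function(x) {
  if (is.null(x)) return(NULL)
  solution_composition(unlist(x$components), pH = x$pH, ljp = x$ljp,
                       titrant = x$titrant)
}

rebuild_protocol <- function(x) {
  if (is.null(x)) return(NULL)
  x$epochs <- lapply(x$epochs, function(e) {
    e$v_start <- unlist(e$v_start); e$v_end <- unlist(e$v_end); e
  })
  if (!is.null(x$levels)) x$levels <- unlist(x$levels)
  structure(x, class = "voltage_protocol")
}

#' Read a sweep set from a sweep-table file
#'
#' Malformed lines (wrong field count, non-numeric data) raise a parse error
#' naming the offending line. A missing sidecar loads the traces with a
#' warning; analysis stages that need protocol or conditions metadata will
#' refuse such a sweep set.
#'
#' @param path Sweep-table file written by [write_sweepset()].
#' @return A `sweep_set`.
#' @export
read_sweepset <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("parse error: no data lines in ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  nf <- length(header)
  if (header[1] != "time_ms") {
    stop("parse error at line 1: first column must be 'time_ms'")
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  for (k in seq_along(rows)) {
    if (length(rows[[k]]) != nf) {
      stop("parse error at line ", k + 1, ": expected ", nf, " fields, got ",
           length(rows[[k]]))
    }
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = nf,
              byrow = TRUE)
  bad <- which(apply(is.na(m), 1, any))
  if (length(bad)) {
    stop("parse error at line ", bad[1] + 1, ": non-numeric field")
  }
  colnames(m) <- header
  is_sub <- grepl("_p4_", header)
  main_cols <- which(!is_sub & header != "time_ms")
  meta_path <- paste0(path, ".meta.json")
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE)
  } else {
    warning("sidecar metadata ", meta_path, " not found; loading traces ",
            "only (stages requiring protocol/conditions will refuse)")
  }
  subsweeps <- NULL
  if (any(is_sub)) {
    subsweeps <- lapply(seq_along(main_cols), function(s) {
      cols <- which(grepl(sprintf("^sw%02d_p4_", s), header))
      m[, cols, drop = FALSE]
    })
  }
  cond <- NULL
  if (!is.null(meta$conditions)) {
    cond <- structure(meta$conditions, class = "recording_conditions")
  }
  structure(
    list(time_ms = m[, 1], current_pA = m[, main_cols, drop = FALSE],
         protocol = rebuild_protocol(meta$protocol),
         internal = rebuild_solution(meta$internal),
         external = rebuild_solution(meta$external),
         conditions = cond, drug = meta$drug,
         channel_name = meta$channel_name,
         subsweeps = subsweeps,
         p4_subtracted = isTRUE(meta$p4_subtracted)),
    class = "sweep_set"
  )
}

#' Run an analysis scenario from a configuration
#'
#' Executes simulate -> process -> analysis for one of the packaged
#' scenarios, deterministically from the config and its seed. Every output
#' table carries the config hash and seed as attributes; rerunning the same
#' config reproduces identical results. A stage failure is recorded in the
#' log, downstream stages are skipped, and `status` is nonzero.
#'
#' @param config A named list, or path to a YAML file, with at least
#'   `scenario` (`"selectivity"`, `"gating"`, `"q10"` or `"dose"`),
#'   `channel` (preset name) and `seed`. Scenario-specific fields: `ions`
#'   (selectivity), `temps` and `phs` (q10), `drugs` and `doses` (dose),
#'   `phs` (gating). Optional `out_dir` writes the tables as delimited text.
#' @return List of class `pipeline_result`: `tables` (named list of data
#'   frames), `log` (data frame), `config_hash`, `seed`, `status` (0 ok,
#'   1 analysis failure).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$scenario),
            !is.null(config$channel))
  if (is.null(config$seed)) stop("config must set a seed")
  hash <- rlang::hash(config)
  channel <- channel_preset(config$channel)
  seed <- as.integer(config$seed)
  log <- data.frame(stage = character(), status = character(),
                    message = character(), seconds = numeric())
  tables <- list()
  status <- 0L
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      log <<- rbind(log, data.frame(stage = name, status = "error",
                                    message = conditionMessage(res),
                                    seconds = dt))
      status <<- 1L
      NULL
    } else {
      log <<- rbind(log, data.frame(stage = name, status = "ok",
                                    message = "", seconds = dt))
      res
    }
  }
  cond <- recording_conditions(
    temperature = config$temperature %||% 22,
    noise_sd_pA = config$noise_sd %||% 2,
    seed = seed)
  if (config$scenario == "selectivity") {
    ions <- unlist(config$ions %||% c("Li", "Na", "K", "Rb", "Cs"))
    tab <- run_stage("selectivity", function() {
      selectivity_panel(channel, ions, conditions = cond)
    })
    if (!is.null(tab)) tables$selectivity <- tab
  } else if (config$scenario == "q10") {
    temps <- unlist(config$temps %||% seq(20, 36, 4))
    phs <- unlist(config$phs %||% c(7.4, 9.4))
    rows <- list()
    for (ph in phs) {
      series <- run_stage(paste0("ramp_series_pH", ph), function() {
        simulate_ramp_series(channel, temps, pH = ph, conditions = cond)
      })
      if (is.null(series)) break
      qr <- run_stage(paste0("q10_pH", ph), function() {
        q10_analysis(series$temp_c, series$peak_pA_abs, label = paste0("pH", ph))
      })
      if (is.null(qr)) break
      rows[[length(rows) + 1]] <- data.frame(
        channel = channel$name, pH = ph, q10 = qr$q10,
        q10_two_point = qr$q10_two_point, n_temps = qr$n)
    }
    if (length(rows)) tables$q10 <- do.call(rbind, rows)
  } else if (config$scenario == "gating") {
    phs <- unlist(config$phs %||% c(7.4, 9.4))
    rows <- lapply(phs, function(ph) {
      run_stage(paste0("gating_pH", ph), function() {
        gating_summary(channel, conditions = cond, pH = ph)
      })
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) tables$gating <- do.call(rbind, rows)
  } else if (config$scenario == "dose") {
    drugs <- unlist(config$drugs %||% names(channel$drug_sensitivity))
    doses <- unlist(config$doses %||% c(3, 10, 30, 100, 300, 1000))
    rows <- lapply(drugs, function(d) {
      run_stage(paste0("dose_", d), function() {
        dr <- simulate_block_dose_response(channel, d, doses, cond)
        hf <- fit_hill(dr$dose_uM, dr$response_pct)
        data.frame(drug = d, assay = "current_block", ec50_uM = hf$ec50_uM,
                   hill_n = hf$hill_n, ok = hf$ok)
      })
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) tables$dose <- do.call(rbind, rows)
  } else {
    stop("unknown scenario: ", config$scenario)
  }
  tables <- lapply(tables, function(tb) {
    attr(tb, "config_hash") <- hash
    attr(tb, "seed") <- seed
    tb
  })
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      f <- file.path(config$out_dir, paste0(nm, ".tsv"))
      utils::write.table(
        cbind(tables[[nm]], config_hash = hash, seed = seed), f,
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    utils::write.table(log, file.path(config$out_dir, "run_log.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  structure(list(tables = tables, log = log, config_hash = hash,
                 seed = seed, status = status),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
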