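# CSV I/O with provenance comment headers and a config-driven pipeline runner.
# Output is RFC-4180-style CSV, UTF-8, "." decimal; provenance headers carry
# the package version, seed and parameters (no timestamps, so identical
# configurations give byte-identical files).

provenance_header <- function(seed = NULL, params = NULL) {
  bits <- c(sprintf("# wtfdrive %s", as.character(packageVersion("wtfdrive"))))
  if (!is.null(seed)) bits <- c(bits, sprintf("# seed: %s", seed))
  if (!is.null(params) && length(params)) {
    bits <- c(bits, sprintf("# params: %s",
                            paste(names(params), unlist(params),
                                  sep = "=", collapse = " ")))
  }
  bits
}

write_provenance_csv <- function(tbl, path, seed = NULL, params = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed, params), con)
  write.csv(tbl, con, row.names = FALSE)
  invisible(path)
}

#' Read a spore genotype count table from CSV
#'
#' Reads a count table in the layout of the study's source-data files: a
#' header-declared schema with one row per diploid and one column per
#' marker-phenotype class. Lines starting with `#` (provenance headers) are
#' skipped. Counts must be non-negative integers; violations are reported with
#' their row and column. Unknown columns are preserved as pass-through
#' metadata.
#'
#' @param path CSV file path.
#' @param single Character vector naming the single-marker class columns.
#' @param double Name of the double-marker class column (default
#'   `"both_markers"` if present).
#' @param no_marker Optional marker-less class column (default `"no_marker"`
#'   if present).
#' @param id Diploid identifier column (default `"diploid"`).
#' @return A tibble carrying its schema as the `count_schema` attribute.
#' @export
read_count_table <- function(path, single = NULL, double = NULL,
                             no_marker = NULL, id = "diploid") {
  raw <- read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  tbl <- as_tibble(raw)
  if (!id %in% names(tbl)) {
    abort(sprintf("Count table must have an identifier column '%s'.", id))
  }
  if (is.null(double) && "both_markers" %in% names(tbl)) double <- "both_markers"
  if (is.null(no_marker) && "no_marker" %in% names(tbl)) no_marker <- "no_marker"
  if (is.null(single)) {
    single <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))],
                      c(double, no_marker))
  }
  for (col in c(single, double, no_marker)) {
    if (!col %in% names(tbl)) {
      abort(sprintf("Declared class column '%s' is missing.", col))
    }
    v <- tbl[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad)) {
      abort(sprintf("Invalid count in column '%s', row %d: %s (counts must be non-negative integers).",
                    col, bad[1], v[bad[1]]))
    }
    tbl[[col]] <- as.integer(v)
  }
  attr(tbl, "count_schema") <- list(single = single, double = double,
                                    no_marker = no_marker, id = id)
  tbl
}

#' Write a spore genotype count table to CSV
#'
#' Inverse of [read_count_table()]: writes the class counts with a provenance
#' comment header. `read_count_table(write_count_table(tbl, path))` restores
#' the table and its schema.
#'
#' @param tbl A count table (with a `count_schema` attribute, as produced by
#'   [synth_count_table()] or [read_count_table()]).
#' @param path Output CSV path.
#' @param seed Optional seed recorded in the provenance header.
#' @return The path, invisibly.
#' @export
write_count_table <- function(tbl, path, seed = NULL) {
  write_provenance_csv(tbl, path, seed = seed)
}

#' Run a configured pipeline step
#'
#' Dispatches the package's analyses from a single configuration list (or YAML
#' file with the same fields), writing CSV artifacts with provenance headers.
#' Identical configuration and seed give byte-identical outputs.
#'
#' Subcommands and their fields:
#' \describe{
#'   \item{`enumerate`}{`scenario` (library name): exact census CSV.}
#'   \item{`simulate`}{`scenario`, `n_meioses`, `seed`: sampled census CSV.}
#'   \item{`synth`}{`scenario`, `seed` (optional `n_spores`): synthetic count
#'     table CSV in the schema `analyze` reads.}
#'   \item{`analyze`}{`input` (count-table CSV), optional `control` (diploid id
#'     of the control row): per-diploid disomy, transmission and G-test CSV.}
#'   \item{`fit`}{`input` (count-table CSV), optional `driver`/`nondriver`:
#'     drive-strength estimates CSV.}
#'   \item{`popgen-trajectory`}{model parameter fields (`n`, `t`, `f`, `h`,
#'     `s_m`, `s_s`, `p0`): per-generation trajectory CSV with the outcome.}
#'   \item{`popgen-phase`}{`n` and `t` vectors plus fixed parameters: invasion
#'     grid CSV.}
#' }
#'
#' @param config A named list with at least `subcommand` and `output`, or the
#'   path to a YAML file parseable to one (requires the yaml package).
#' @return The output path, invisibly.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configs requires the yaml package.")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$subcommand) || is.null(config$output)) {
    abort("`config` must name a `subcommand` and an `output` path.")
  }
  sub <- config$subcommand
  out <- config$output
  seed <- config$seed
  get_scenario <- function() {
    lib <- scenario_library()
    s <- lib[[config$scenario]]
    if (is.null(s)) {
      abort(sprintf("Unknown scenario '%s'. Available: %s", config$scenario,
                    paste(names(lib), collapse = ", ")))
    }
    if (!is.null(config$n_spores)) s$n_spores <- as.integer(config$n_spores)
    s
  }
  mp <- function() {
    model_params(
      n = config$n %||% 3, t = config$t %||% 0.95, f = config$f %||% 1,
      h = config$h %||% 0.5, s_m = config$s_m %||% 0, s_s = config$s_s %||% 0,
      p0 = config$p0 %||% 0.1)
  }
  flatten_census <- function(cen) {
    cen$markers <- vapply(cen$markers, function(m) {
      paste(m[!is.na(m)], collapse = ";")
    }, character(1))
    cen
  }

  if (sub == "enumerate") {
    s <- get_scenario()
    write_provenance_csv(flatten_census(enumerate_meiosis(s$cross)), out,
                         params = list(scenario = s$name))
  } else if (sub == "simulate") {
    if (is.null(seed)) abort("`simulate` requires a `seed`.")
    s <- get_scenario()
    n <- as.integer(config$n_meioses %||% 1e4)
    write_provenance_csv(flatten_census(simulate_meioses(s$cross, n, seed)), out,
                         seed = seed, params = list(scenario = s$name, n_meioses = n))
  } else if (sub == "synth") {
    if (is.null(seed)) abort("`synth` requires a `seed`.")
    s <- get_scenario()
    write_count_table(synth_count_table(s, seed), out, seed = seed)
  } else if (sub == "analyze") {
    tbl <- read_count_table(config$input)
    sch <- attr(tbl, "count_schema")
    dis <- disomy_frequency(tbl)
    tr <- allele_transmission(tbl, marker = sch$single[1])
    res <- dis |>
      left_join(select(tr, !!sch$id, marker, n_haploid, transmission),
                by = sch$id) |>
      rowwise() |>
      mutate(
        g_transmission_p = if (.data$n_haploid > 0)
          g_test(c(.data$transmission, 1 - .data$transmission) * .data$n_haploid)$p.value
        else NA_real_
      ) |>
      ungroup()
    if (!is.null(config$control)) {
      ctrl <- res[res[[sch$id]] == config$control, ]
      if (nrow(ctrl) == 1 && ctrl$n_double > 0 && ctrl$n_double < ctrl$n_total) {
        p_ctrl <- ctrl$n_double / ctrl$n_total
        res <- res |>
          rowwise() |>
          mutate(g_disomy_vs_control_p = g_test(
            c(.data$n_double, .data$n_total - .data$n_double),
            expected = c(p_ctrl, 1 - p_ctrl))$p.value) |>
          ungroup()
      }
    }
    write_provenance_csv(res, out, params = list(input = config$input))
  } else if (sub == "fit") {
    tbl <- read_count_table(config$input)
    fit <- fit_drive_strength(tbl, driver = config$driver,
                              nondriver = config$nondriver)
    write_provenance_csv(tidy(fit), out, params = list(input = config$input))
  } else if (sub == "popgen-trajectory") {
    traj <- drive_trajectory(mp(), max_gen = config$max_gen %||% 1e5)
    states <- tidy(traj)
    states$outcome <- traj$outcome
    write_provenance_csv(states, out, params = unclass(traj$params))
  } else if (sub == "popgen-phase") {
    grid <- phase_grid(
      n = config$n %||% 2:10,
      t = config$t %||% seq(0, 1, length.out = 101),
      f = config$f %||% 1, h = config$h %||% 0.5,
      s_m = config$s_m %||% 0, s_s = config$s_s %||% 0)
    write_provenance_csv(as_tibble(grid), out)
  } else {
    abort(sprintf("Unknown subcommand '%s'.", sub))
  }
  invisible(out)
}
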