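# Rate-constant table IO and the per-enzyme analysis pipeline.
#
# Input schema (header mandatory, UTF-8, decimal point):
#   required columns  name, n_states, k1..k8   (unused constants blank
#                     for 2- and 3-state rows)
#   optional columns  k1_second_order, S_conc, k_last_second_order, P_conc,
#                     class, evo_distance
# Rows that fail validation are rejected individually with a row-level
# report; the reader never aborts on one bad row and never coerces silently.

SCHEMA_VERSION <- "1.0"

cd_log <- function(level, ...) {
  levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, NONE = 4L)
  cur <- getOption("cycledissip.log_level", "INFO")
  if (levels[[level]] >= levels[[cur]])
    message(sprintf("[%s] %s", level, sprintf(...)))
  invisible(NULL)
}

#' Read a rate-constant table
#'
#' Parses a CSV/TSV of microscopic rate constants, one enzyme per row, into
#' validated [cycle_scheme()] objects. A missing required column is a hard
#' failure naming the column; an invalid row (non-numeric or nonpositive
#' rate, bad `n_states`, duplicate name, inconsistent binding declaration)
#' is rejected with a machine-readable reason and does not abort the read.
#'
#' When `k1_second_order` and `S_conc` are absent the substrate-binding
#' edge is declared at a nominal `[S] = 1 M` with `k1* = k1`, so specificity
#' constants are reported per molar of the stated working substrate; a WARN
#' entry records the assumption.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension; default), `"csv"`, or `"tsv"`.
#' @return an object of class `enzyme_table`: `entries` (list of
#'   `list(name, scheme, class_label, evo_distance)`), `rejected`
#'   (data frame `row`, `name`, `column`, `reason`), `source`,
#'   `schema_version`.
#' @export
read_enzyme_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "tsv" else "csv"
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("name", "n_states", paste0("k", 1:8))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  cd_log("INFO", "read %d row(s) from %s", nrow(raw), path)

  entries <- list()
  rejected <- data.frame(row = integer(), name = character(),
                         column = character(), reason = character(),
                         stringsAsFactors = FALSE)
  reject <- function(i, nm, col, why) {
    rejected[nrow(rejected) + 1L, ] <<- list(i, nm, col, why)
    cd_log("WARN", "row %d (%s): rejected [%s: %s]", i, nm, col, why)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  seen <- character()

  for (i in seq_len(nrow(raw))) {
    nm <- trimws(raw$name[i])
    if (!nzchar(nm)) { reject(i, "", "name", "empty name"); next }
    if (nm %in% seen) { reject(i, nm, "name", "duplicate name"); next }
    ns <- num(raw$n_states[i])
    if (is.na(ns) || !(ns %in% 2:4)) {
      reject(i, nm, "n_states", "n_states must be 2, 3, or 4"); next
    }
    ns <- as.integer(ns)
    kcols <- paste0("k", seq_len(2L * ns))
    kv <- num(unlist(raw[i, kcols]))
    if (any(is.na(kv))) {
      reject(i, nm, kcols[which(is.na(kv))[1]], "non-numeric rate constant"); next
    }
    if (any(kv <= 0)) {
      reject(i, nm, kcols[which(kv <= 0)[1]], "nonpositive rate constant"); next
    }
    fwd <- kv[seq(1L, 2L * ns, by = 2L)]
    rev <- kv[seq(2L, 2L * ns, by = 2L)]

    sub <- NULL; prod <- NULL
    k1s <- if ("k1_second_order" %in% names(raw)) num(raw$k1_second_order[i]) else NA
    Sc <- if ("S_conc" %in% names(raw)) num(raw$S_conc[i]) else NA
    if (!is.na(k1s) && !is.na(Sc)) {
      sub <- list(k2nd = k1s, conc = Sc)
    } else {
      sub <- list(k2nd = fwd[1], conc = 1)
      cd_log("WARN", "row %d (%s): no second-order substrate data; assuming [S] = 1 M", i, nm)
    }
    kps <- if ("k_last_second_order" %in% names(raw)) num(raw$k_last_second_order[i]) else NA
    Pc <- if ("P_conc" %in% names(raw)) num(raw$P_conc[i]) else NA
    if (!is.na(kps) && !is.na(Pc)) prod <- list(k2nd = kps, conc = Pc)

    sch <- tryCatch(
      cycle_scheme(fwd, rev, substrate = sub, product = prod, name = nm),
      error = function(e) conditionMessage(e))
    if (is.character(sch)) { reject(i, nm, "*", sch); next }

    cl <- if ("class" %in% names(raw)) trimws(raw$class[i]) else ""
    if (!nzchar(cl) || is.na(cl)) cl <- "unknown"
    if (!cl %in% c("specialist", "generalist", "mutant", "wild-type", "unknown")) {
      reject(i, nm, "class", sprintf("unknown class label '%s'", cl)); next
    }
    ed <- if ("evo_distance" %in% names(raw)) num(raw$evo_distance[i]) else NA_real_
    seen <- c(seen, nm)
    entries[[length(entries) + 1L]] <-
      list(name = nm, scheme = sch, class_label = cl, evo_distance = ed)
  }
  cd_log("INFO", "parsed %d valid, rejected %d", length(entries), nrow(rejected))
  structure(list(entries = entries, rejected = rejected, source = path,
                 schema_version = SCHEMA_VERSION),
            class = "enzyme_table")
}

#' @export
print.enzyme_table <- function(x, ...) {
  cat(sprintf("<enzyme_table: %d enzyme(s), %d rejected row(s), schema %s>\n",
              length(x$entries), nrow(x$rejected), x$schema_version))
  invisible(x)
}

#' Write schemes to the standard rate-constant table
#'
#' Inverse of [read_enzyme_table()]; values are written with 17 significant
#' digits so a read-back round trip reproduces them to full double
#' precision.
#'
#' @param x an `enzyme_table`, a list of [cycle_scheme()] objects, or a
#'   single scheme.
#' @param path output file path (`.tsv` extension selects tab separation).
#' @return `path`, invisibly.
#' @export
write_enzyme_table <- function(x, path) {
  if (inherits(x, "cycle_scheme")) x <- list(x)
  if (inherits(x, "enzyme_table")) {
    rows <- x$entries
  } else {
    rows <- lapply(seq_along(x), function(i) {
      sch <- x[[i]]
      nm <- if (!is.null(sch$name)) sch$name
            else if (!is.null(names(x)) && nzchar(names(x)[i])) names(x)[i]
            else sprintf("enzyme_%03d", i)
      list(name = nm, scheme = sch, class_label = "unknown", evo_distance = NA_real_)
    })
  }
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  df <- do.call(rbind, lapply(rows, function(e) {
    s <- e$scheme; n <- s$n_states
    k <- rep(NA_real_, 8L)
    k[seq(1L, 2L * n, by = 2L)] <- s$forward
    k[seq(2L, 2L * n, by = 2L)] <- s$reverse
    data.frame(
      name = e$name, n_states = n,
      k1 = fmt(k[1]), k2 = fmt(k[2]), k3 = fmt(k[3]), k4 = fmt(k[4]),
      k5 = fmt(k[5]), k6 = fmt(k[6]), k7 = fmt(k[7]), k8 = fmt(k[8]),
      k1_second_order = fmt(if (is.null(s$substrate)) NA else s$substrate$k2nd),
      S_conc = fmt(if (is.null(s$substrate)) NA else s$substrate$conc),
      k_last_second_order = fmt(if (is.null(s$product)) NA else s$product$k2nd),
      P_conc = fmt(if (is.null(s$product)) NA else s$product$conc),
      class = e$class_label,
      evo_distance = fmt(e$evo_distance),
      stringsAsFactors = FALSE)
  }))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full per-enzyme analysis pipeline
#'
#' For every valid table entry, solves the steady state and computes the
#' catalytic parameters; per-row failures are isolated and logged, never
#' fatal. The result carries a summary block with counts by class label and
#' the count of rows whose backward-flux diagnostic `kcat/J` exceeds
#' `kcat_over_J_threshold` (default 2.0, the level above which backward
#' cycling is clearly non-negligible), plus per-class median dissipation
#' and the specialist/generalist median ratio when both classes are present.
#'
#' @param table an `enzyme_table` from [read_enzyme_table()], or a list of
#'   [cycle_scheme()] objects.
#' @param kcat_over_J_threshold threshold for the backward-flux count.
#' @return a `pipeline_results` data frame (one row per enzyme; columns for
#'   all steady-state and kinetic-summary fields, `p1..p4` and
#'   `sigma1..sigma4` padded with `NA` beyond the scheme size) with
#'   attributes `summary` and `schema_version`.
#' @export
run_pipeline <- function(table, kcat_over_J_threshold = 2.0) {
  if (inherits(table, "cycle_scheme")) table <- list(table)
  if (!inherits(table, "enzyme_table")) {
    entries <- lapply(seq_along(table), function(i) {
      nm <- if (!is.null(table[[i]]$name)) table[[i]]$name else sprintf("enzyme_%03d", i)
      list(name = nm, scheme = table[[i]], class_label = "unknown",
           evo_distance = NA_real_)
    })
  } else entries <- table$entries
  cd_log("INFO", "pipeline: %d enzyme(s) in", length(entries))

  rows <- vector("list", length(entries))
  failures <- data.frame(name = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    out <- tryCatch({
      st <- solve_steady_state(e$scheme)
      ks <- catalytic_parameters(e$scheme, class_label = e$class_label,
                                 evo_distance = e$evo_distance)
      n <- e$scheme$n_states
      p <- sig <- rep(NA_real_, 4L)
      p[seq_len(n)] <- st$probabilities
      sig[seq_len(n)] <- st$edge_sigma_RT
      data.frame(name = e$name, n_states = n, class_label = e$class_label,
                 evo_distance = e$evo_distance,
                 kcat = ks$kcat, KM = ks$KM, kcat_KM = ks$kcat_KM,
                 J = st$J, J_plus = st$J_plus, J_minus = st$J_minus,
                 X_RT = st$X_RT, dissipation_RT = st$dissipation_RT,
                 kcat_over_J = ks$kcat_over_J,
                 backward_driven = ks$backward_driven,
                 p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4],
                 sigma1 = sig[1], sigma2 = sig[2], sigma3 = sig[3],
                 sigma4 = sig[4], stringsAsFactors = FALSE)
    }, error = function(err) conditionMessage(err))
    if (is.character(out)) {
      cd_log("WARN", "pipeline: %s failed [%s]", e$name, out)
      failures[nrow(failures) + 1L, ] <- list(e$name, out)
    } else rows[[i]] <- out
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) res <- data.frame()

  n_gt <- if (nrow(res)) sum(is.finite(res$kcat_over_J) &
                             res$kcat_over_J > kcat_over_J_threshold) else 0L
  med_by_class <- if (nrow(res))
    tapply(res$dissipation_RT, res$class_label, stats::median) else numeric()
  ratio <- if (all(c("specialist", "generalist") %in% names(med_by_class)))
    unname(med_by_class[["specialist"]] / med_by_class[["generalist"]]) else NA_real_

  summary <- list(
    n_input = length(entries), n_ok = nrow(res), n_failed = nrow(failures),
    failures = failures,
    class_counts = if (nrow(res)) table(res$class_label) else table(character()),
    kcat_over_J_threshold = kcat_over_J_threshold,
    n_kcat_over_J_above_threshold = n_gt,
    median_dissipation_by_class = med_by_class,
    specialist_generalist_median_ratio = ratio)
  cd_log("INFO", "pipeline: %d ok, %d failed; %d row(s) with kcat/J > %.2g",
         nrow(res), nrow(failures), n_gt, kcat_over_J_threshold)
  structure(res, summary = summary, schema_version = SCHEMA_VERSION,
            class = c("pipeline_results", "data.frame"))
}

#' @export
print.pipeline_results <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<pipeline_results: %d/%d enzyme(s) computed, %d failed>\n",
              s$n_ok, s$n_input, s$n_failed))
  cat(sprintf("  kcat/J > %.2g on %d row(s)\n",
              s$kcat_over_J_threshold, s$n_kcat_over_J_above_threshold))
  if (is.finite(s$specialist_generalist_median_ratio))
    cat(sprintf("  specialist/generalist median dissipation ratio = %.3g\n",
                s$specialist_generalist_median_ratio))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 10))
  invisible(x)
}

#' Write pipeline results
#'
#' CSV (one row per enzyme, `schema_version` column stamped) or JSON
#' (object with `schema_version`, `summary`, `results`).
#'
#' @param results a [run_pipeline()] result.
#' @param path output path; format chosen by `.json` / `.csv` extension
#'   unless `format` is given.
#' @param format `"auto"`, `"csv"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  s <- attr(results, "summary")
  df <- as.data.frame(results)
  if (format == "csv") {
    df$schema_version <- SCHEMA_VERSION
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(schema_version = SCHEMA_VERSION,
           summary = list(
             n_input = s$n_input, n_ok = s$n_ok, n_failed = s$n_failed,
             class_counts = as.list(s$class_counts),
             kcat_over_J_threshold = s$kcat_over_J_threshold,
             n_kcat_over_J_above_threshold = s$n_kcat_over_J_above_threshold,
             specialist_generalist_median_ratio = s$specialist_generalist_median_ratio),
           results = df),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
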