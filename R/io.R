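#' Default column synonym map for morphometric tables
#'
#' Maps the canonical column names (`specimen_id`, `species`, `wingspan`,
#' `wing_length`, `s1`, `units`) to accepted header spellings. Headers are
#' matched case-insensitively after dropping parenthesized unit notes and
#' normalizing separators, so `"Wing.Length"` and `"wing length (mm)"`
#' both resolve to `wing_length`. Pass an edited copy to
#' [read_morphometrics()] to extend it.
#'
#' @return A named list of character vectors.
#' @export
default_synonyms <- function() {
  list(
    specimen_id = c("specimen_id", "id", "specimen", "catalog", "catalog_no"),
    species = c("species", "taxon", "binomial", "scientific_name"),
    wingspan = c("wingspan", "ws", "wing_span"),
    wing_length = c("wing_length", "wl", "winglength"),
    s1 = c("s1", "wing_width", "secondary1", "s1_length"),
    units = c("units", "unit")
  )
}

normalize_header <- function(h) {
  h <- tolower(gsub("\\(.*?\\)", "", h))
  h <- gsub("[^a-z0-9]+", "_", h)
  gsub("^_+|_+$", "", h)
}

#' Read a folded-wing morphometric table
#'
#' Reads a comma- or tab-delimited table of folded-wing measurements,
#' resolves headers through the synonym map, converts units to cm, and
#' drops rows with missing or non-positive measurements (with a warning
#' listing them; nothing is imputed).
#'
#' @param path Delimited text file. The delimiter is auto-detected
#'   (comma or tab); decimal separator must be `.`.
#' @param units `"cm"` or `"mm"`. If `NULL` (default), a `units` column
#'   is honored if present, otherwise cm is assumed.
#' @param synonyms Header synonym map, see [default_synonyms()].
#' @return Data frame with columns `specimen_id`, `species`, `wingspan`,
#'   `wing_length`, `s1` (all cm) and attribute `rejected` holding the
#'   skipped row numbers.
#' @export
read_morphometrics <- function(path, units = NULL,
                               synonyms = default_synonyms()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  hdr <- normalize_header(names(raw))
  as_measurement <- function(v) {
    if (is.character(v) && any(grepl(",", v, fixed = TRUE))) {
      stop("locale decimal commas detected; use '.' as the decimal ",
           "separator", call. = FALSE)
    }
    suppressWarnings(as.numeric(v))
  }
  resolve <- function(canon) {
    hit <- which(hdr %in% normalize_header(synonyms[[canon]]))
    if (length(hit)) hit[1L] else NA_integer_
  }
  idx <- vapply(names(default_synonyms()), resolve, 1L)
  required <- c("wingspan", "wing_length", "s1")
  if (any(is.na(idx[required]))) {
    stop("schema error: missing required column(s) ",
         paste(required[is.na(idx[required])], collapse = ", "),
         "; headers found: ", paste(names(raw), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    specimen_id = if (is.na(idx["specimen_id"])) {
      sprintf("row%03d", seq_len(nrow(raw)))
    } else as.character(raw[[idx["specimen_id"]]]),
    species = if (is.na(idx["species"])) NA_character_
              else as.character(raw[[idx["species"]]]),
    wingspan = as_measurement(raw[[idx["wingspan"]]]),
    wing_length = as_measurement(raw[[idx["wing_length"]]]),
    s1 = as_measurement(raw[[idx["s1"]]]),
    stringsAsFactors = FALSE
  )
  file_units <- if (!is.null(units)) {
    rep(match.arg(units, c("cm", "mm")), nrow(out))
  } else if (!is.na(idx["units"])) {
    tolower(as.character(raw[[idx["units"]]]))
  } else rep("cm", nrow(out))
  if (!all(file_units %in% c("cm", "mm"))) {
    stop("unsupported units: ", paste(setdiff(file_units, c("cm", "mm")),
                                      collapse = ", "), call. = FALSE)
  }
  fac <- ifelse(file_units == "mm", 0.1, 1)
  for (v in required) out[[v]] <- out[[v]] * fac
  bad <- !stats::complete.cases(out[required]) |
    out$wingspan <= 0 | out$wing_length <= 0 | out$s1 <= 0
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning("skipping ", sum(bad), " row(s) with missing or non-positive ",
            "measurements: ", paste(which(bad), collapse = ", "),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "rejected") <- which(bad)
  out
}

#' Write a morphometric or results table
#'
#' Plain CSV writer (no row names, full precision) so that a write/read
#' round trip preserves values exactly.
#'
#' @param data Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_morphometrics <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Parses with [ape::read.tree()] and validates the invariants the
#' comparative analyses rely on: branch lengths present and non-negative,
#' unique tip labels.
#'
#' @param path Newick file (or a Newick string via `text`).
#' @param text Optional Newick string instead of a file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("parse error: not a valid Newick tree", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("parse error: tree has no branch lengths", call. = FALSE)
  }
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("parse error: missing or negative branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("parse error: duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tree
}

#' Resolved run configuration
#'
#' Collects the options that govern a run into a serializable list, with
#' the package version attached, so every report can state exactly how it
#' was produced.
#'
#' @param units Input units, `"cm"` or `"mm"`.
#' @param model Planform model name.
#' @param diff_mode Percent-difference mode, see [intraspecific_summary()].
#' @param box_policy Medial-box policy, see [medial_box_area()].
#' @param seed Integer seed (or `NA`).
#' @param ... Further named options to record.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(units = "cm", model = "ellipse-triangle",
                       diff_mode = "ratio-of-means", box_policy = "strict",
                       seed = NA_integer_, ...) {
  structure(list(units = units, model = planform_model(model)$name,
                 diff_mode = diff_mode, box_policy = box_policy,
                 seed = seed,
                 version = as.character(utils::packageVersion("wingplan")),
                 ...),
            class = "run_config")
}

#' Write a run report as CSV and JSON
#'
#' Serializes a result table (CSV) together with a JSON document holding
#' the same values plus the resolved configuration. Output contains no
#' timestamps, so identical inputs yield byte-identical reports.
#'
#' @param results A data frame (e.g. from [compare_methods()]) or a
#'   `pgls_fit`.
#' @param csv_path,json_path Output files; either may be `NULL` to skip.
#' @param config A [run_config()].
#' @return Invisible list of the paths written.
#' @export
run_report <- function(results, csv_path = NULL, json_path = NULL,
                       config = run_config()) {
  if (inherits(results, "pgls_fit")) {
    tab <- data.frame(
      term = names(results$coefficients),
      estimate = unname(results$coefficients),
      se = unname(results$se),
      r2 = results$r2, lambda = results$lambda %||% NA_real_,
      logLik = results$logLik, aicc = results$aicc %||% NA_real_,
      n = results$n, k = results$k %||% NA_integer_,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- as.data.frame(results)
  }
  if (!is.null(csv_path)) write_morphometrics(tab, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(config = unclass(config), results = tab),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(list(csv = csv_path, json = json_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published intraspecific reference summaries
#'
#' Published mean and sample-standard-deviation summaries of total wing
#' area (cm^2) for three intraspecific specimen series — a hummingbird
#' (*Archilochus colubris*, n = 17), a pigeon (*Columba livia*, n = 18),
#' and a jay (*Cyanocitta cristata*, n = 16) — measured with the
#' spread-wing method and with the three folded-wing models. Shipped as a
#' plain-text table for internal-consistency checks of the comparison
#' statistics (recomputing CVs and percent differences from the printed
#' means and SDs).
#'
#' @return Data frame with columns `species`, `n`, `method`, `mean`,
#'   `sd`, `printed_cv`, `printed_pct_diff` (percent difference is `NA`
#'   for the spread-wing rows).
#' @export
reference_summaries <- function() {
  path <- system.file("extdata", "intraspecific_reference.csv",
                      package = "wingplan", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
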