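# Readers and writers for the pipeline's tabular interchange formats.
#
# All formats are delimited text (TAB by default); lines starting with '#'
# are comments; identifiers are opaque case-sensitive strings.

# Split a delimited file into a list of character vectors, keeping original
# line numbers for error reporting. Comment and blank lines are dropped.
read_delim_rows <- function(path, delimiter = "\t", n_cols, what) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stopf("%s: no data rows in '%s'", what, path)
  rows <- strsplit(lines[keep], delimiter, fixed = TRUE)
  lineno <- which(keep)
  bad <- which(lengths(rows) != n_cols |
                 vapply(rows, function(r) any(!nzchar(r)), logical(1)))
  if (length(bad)) {
    stopf("%s: line %d of '%s' does not have %d non-empty columns",
          what, lineno[bad[1]], path, n_cols)
  }
  list(rows = rows, lineno = lineno)
}

has_header <- function(row, numeric_cols = integer()) {
  # A header row is detected when a column that must be numeric is not.
  if (!length(numeric_cols)) return(FALSE)
  any(is.na(suppressWarnings(as.numeric(row[numeric_cols]))))
}

#' Construct a binary occurrence profile
#'
#' An occurrence profile records which entities (drugs or diseases) display
#' which features (side effects or symptoms) as a sparse binary incidence
#' matrix with features as rows and entities as columns. Both axes are
#' sorted lexicographically so construction is deterministic.
#'
#' @param entities character vector of entity identifiers, one per incidence.
#' @param features character vector of feature identifiers, parallel to
#'   `entities`.
#' @return An object of class `occurrence_profile`: a list with
#'   `entity_ids`, `feature_ids` and the sparse 0/1 `incidence` matrix
#'   (features x entities).
#' @examples
#' occurrence_profile(c("drugA", "drugA", "drugB"), c("se1", "se2", "se1"))
#' @export
occurrence_profile <- function(entities, features) {
  if (length(entities) != length(features)) {
    stopf("entities and features must have equal length")
  }
  if (!length(entities)) stopf("occurrence profile cannot be empty")
  key <- paste(features, entities, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warnf("dropped %d duplicate incidence row(s)", sum(dup))
    entities <- entities[!dup]
    features <- features[!dup]
  }
  entity_ids <- sort(unique(entities))
  feature_ids <- sort(unique(features))
  incidence <- Matrix::sparseMatrix(
    i = match(features, feature_ids),
    j = match(entities, entity_ids),
    x = 1,
    dims = c(length(feature_ids), length(entity_ids)),
    dimnames = list(feature_ids, entity_ids)
  )
  structure(
    list(entity_ids = entity_ids, feature_ids = feature_ids,
         incidence = incidence),
    class = "occurrence_profile"
  )
}

#' @export
print.occurrence_profile <- function(x, ...) {
  cat(sprintf("<occurrence_profile> %d entities x %d features, %d incidences\n",
              length(x$entity_ids), length(x$feature_ids),
              length(x$incidence@x)))
  invisible(x)
}

#' Read an entity/feature occurrence table
#'
#' Reads a two-column delimited file of (entity, feature) pairs — e.g. a
#' SIDER-style drug/side-effect extract — into an [occurrence_profile()].
#' Duplicate rows are dropped with a single summary warning.
#'
#' @param path path to the delimited file. Lines starting with `#` are
#'   ignored.
#' @param delimiter field separator (default TAB).
#' @param feature_first set `TRUE` if the file lists the feature (side
#'   effect / symptom) in the first column and the entity in the second.
#' @return An `occurrence_profile`.
#' @export
read_occurrence_table <- function(path, delimiter = "\t",
                                  feature_first = FALSE) {
  parsed <- read_delim_rows(path, delimiter, 2L, "occurrence table")
  col1 <- vapply(parsed$rows, `[`, character(1), 1L)
  col2 <- vapply(parsed$rows, `[`, character(1), 2L)
  if (feature_first) {
    occurrence_profile(entities = col2, features = col1)
  } else {
    occurrence_profile(entities = col1, features = col2)
  }
}

#' Read a weighted edge list into an undirected network
#'
#' Expects three columns: node, node, numeric weight in (0, 1]. Duplicate
#' rows for the same unordered pair must agree on the weight; self-loops are
#' dropped with a warning.
#'
#' @inheritParams read_occurrence_table
#' @return An undirected `igraph` graph with an edge attribute `weight`.
#' @export
read_weighted_edgelist <- function(path, delimiter = "\t") {
  parsed <- read_delim_rows(path, delimiter, 3L, "edge list")
  rows <- parsed$rows
  lineno <- parsed$lineno
  if (has_header(rows[[1]], 3L) && length(rows) > 1L) {
    rows <- rows[-1L]
    lineno <- lineno[-1L]
  }
  a <- vapply(rows, `[`, character(1), 1L)
  b <- vapply(rows, `[`, character(1), 2L)
  w <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 3L)))
  if (anyNA(w)) {
    stopf("edge list: non-numeric weight at line %d of '%s'",
          lineno[which(is.na(w))[1]], path)
  }
  bad <- which(w <= 0 | w > 1 + 1e-9)
  if (length(bad)) {
    stopf("edge list: weight %g at line %d of '%s' is outside (0, 1]",
          w[bad[1]], lineno[bad[1]], path)
  }
  w <- pmin(w, 1)
  loops <- a == b
  if (any(loops)) {
    warnf("dropped %d self-loop(s)", sum(loops))
    a <- a[!loops]; b <- b[!loops]; w <- w[!loops]
  }
  if (!length(a)) stopf("edge list: no edges left in '%s'", path)
  key <- pair_key(a, b)
  span <- tapply(w, key, function(v) max(v) - min(v))
  if (any(span > 1e-12)) {
    offender <- names(span)[which(span > 1e-12)[1]]
    stopf("edge list: conflicting weights for duplicated edge (%s)",
          gsub("\r", ", ", offender, fixed = TRUE))
  }
  first <- !duplicated(key)
  edges <- data.frame(from = a[first], to = b[first], weight = w[first],
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

.MARK_LEVELS <- c("M", "T", "M&T", "inferred", "none")
.KNOWN_MARKS <- c("M", "T", "M&T")

normalize_marks <- function(marks) {
  lut <- c(
    "m" = "M", "marker/mechanism" = "M", "marker" = "M",
    "t" = "T", "therapeutic" = "T",
    "m&t" = "M&T", "m/t" = "M&T", "m & t" = "M&T",
    "marker/mechanism|therapeutic" = "M&T",
    "therapeutic|marker/mechanism" = "M&T",
    "marker/mechanism&therapeutic" = "M&T",
    "inferred" = "inferred", "none" = "none"
  )
  out <- lut[tolower(trimws(marks))]
  if (anyNA(out)) {
    offenders <- unique(marks[is.na(out)])
    stopf("unknown curation mark(s): %s",
          paste(sQuote(offenders), collapse = ", "))
  }
  unname(out)
}

#' Construct a curated chemical-disease association set
#'
#' Curation marks follow the CTD vocabulary: `M` (marker/mechanism), `T`
#' (therapeutic), `M&T` (both), `inferred` (computational, not curated) and
#' `none`. Long-form aliases such as `"therapeutic"` or
#' `"marker/mechanism|therapeutic"` are normalized. At most one record per
#' (chemical, disease) pair is allowed; exact duplicates are collapsed,
#' conflicting duplicates raise.
#'
#' @param chemical,disease character identifier vectors of equal length.
#' @param mark character vector of curation marks (aliases accepted).
#' @return A `curated_associations` data frame with columns `chemical`,
#'   `disease`, `mark`.
#' @examples
#' curated_associations("d1", "x1", "therapeutic")
#' @export
curated_associations <- function(chemical, disease, mark) {
  if (length(chemical) != length(disease) ||
      length(chemical) != length(mark)) {
    stopf("chemical, disease and mark must have equal length")
  }
  mark <- normalize_marks(as.character(mark))
  df <- data.frame(chemical = as.character(chemical),
                   disease = as.character(disease),
                   mark = mark, stringsAsFactors = FALSE)
  df <- unique(df)
  key <- paste(df$chemical, df$disease, sep = "\r")
  if (anyDuplicated(key)) {
    offender <- key[duplicated(key)][1]
    stopf("conflicting marks for association (%s)",
          gsub("\r", ", ", offender, fixed = TRUE))
  }
  df <- df[order(df$chemical, df$disease), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("curated_associations", "data.frame")
  df
}

#' Read a CTD-style curated association table
#'
#' Expects three columns: chemical, disease, mark. A header row is detected
#' and skipped when the third field of the first row is not a recognizable
#' mark.
#'
#' @inheritParams read_occurrence_table
#' @return A `curated_associations` data frame.
#' @export
read_curated_associations <- function(path, delimiter = "\t") {
  parsed <- read_delim_rows(path, delimiter, 3L, "association table")
  rows <- parsed$rows
  if (length(rows) > 1L) {
    probe <- try(normalize_marks(rows[[1]][3]), silent = TRUE)
    if (inherits(probe, "try-error")) rows <- rows[-1L]
  }
  curated_associations(
    chemical = vapply(rows, `[`, character(1), 1L),
    disease = vapply(rows, `[`, character(1), 2L),
    mark = vapply(rows, `[`, character(1), 3L)
  )
}

#' Write detected modules to a delimited file
#'
#' Columns: `module_id`, `member_ids` (comma-joined, sorted), `size`,
#' `density`, `cohesiveness`, `p_value`. Numeric columns are written with
#' full precision so that [read_modules()] round-trips exactly.
#'
#' @param modules a `module_set` as returned by [detect_modules()].
#' @param path output path.
#' @param delimiter field separator (default TAB).
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path, delimiter = "\t") {
  if (!inherits(modules, "module_set")) stopf("expected a module_set")
  if (!length(modules$modules)) stopf("refusing to write an empty module set")
  rows <- vapply(modules$modules, function(m) {
    paste(c(m$id, paste(m$members, collapse = ","),
            as.character(length(m$members)),
            fmt_num(c(m$density, m$cohesiveness, m$p_value))),
          collapse = delimiter)
  }, character(1))
  header <- paste(c("module_id", "member_ids", "size", "density",
                    "cohesiveness", "p_value"), collapse = delimiter)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a module table written by [write_modules()]
#'
#' @inheritParams read_occurrence_table
#' @return A `module_set` (with no source-network attribute).
#' @export
read_modules <- function(path, delimiter = "\t") {
  parsed <- read_delim_rows(path, delimiter, 6L, "module table")
  rows <- parsed$rows
  if (identical(rows[[1]][1], "module_id")) rows <- rows[-1L]
  mods <- lapply(rows, function(r) {
    list(id = r[1],
         members = strsplit(r[2], ",", fixed = TRUE)[[1]],
         density = as.numeric(r[4]),
         cohesiveness = as.numeric(r[5]),
         p_value = as.numeric(r[6]))
  })
  new_module_set(mods)
}

#' Write ranked association predictions
#'
#' Columns: `rank`, `drug`, `disease`, `score`, `curated_mark`; scores keep
#' full precision so that [read_predictions()] round-trips exactly.
#'
#' @param predictions a predictions data frame from [predict_associations()]
#'   (columns `rank`, `drug`, `disease`, `score`, `curated_mark`).
#' @inheritParams write_modules
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, delimiter = "\t") {
  need <- c("rank", "drug", "disease", "score", "curated_mark")
  if (!all(need %in% names(predictions))) {
    stopf("predictions must have columns: %s", paste(need, collapse = ", "))
  }
  if (!nrow(predictions)) stopf("refusing to write an empty prediction set")
  rows <- paste(predictions$rank, predictions$drug, predictions$disease,
                fmt_num(predictions$score), predictions$curated_mark,
                sep = delimiter)
  writeLines(c(paste(need, collapse = delimiter), rows), path)
  invisible(path)
}

#' Read a ranked prediction table
#'
#' Accepts the output of [write_predictions()] as well as hand-typed
#' evaluation fixtures with the same five columns.
#'
#' @inheritParams read_occurrence_table
#' @return A data frame of class `association_predictions` ordered by rank.
#' @export
read_predictions <- function(path, delimiter = "\t") {
  parsed <- read_delim_rows(path, delimiter, 5L, "prediction table")
  rows <- parsed$rows
  if (has_header(rows[[1]], c(1L, 4L)) && length(rows) > 1L) rows <- rows[-1L]
  df <- data.frame(
    rank = as.integer(vapply(rows, `[`, character(1), 1L)),
    drug = vapply(rows, `[`, character(1), 2L),
    disease = vapply(rows, `[`, character(1), 3L),
    score = as.numeric(vapply(rows, `[`, character(1), 4L)),
    curated_mark = normalize_marks(vapply(rows, `[`, character(1), 5L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$rank) || anyNA(df$score)) {
    stopf("prediction table: non-numeric rank or score in '%s'", path)
  }
  df <- df[order(df$rank), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("association_predictions", "data.frame")
  df
}
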