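# Relational store for the genomic common data model: nine tables (five
# clinical, four genomic) with primary-key, foreign-key and controlled-
# vocabulary constraints. The schema itself ships as a versioned JSON asset
# under inst/extdata and is loaded once per session.

.gcdm_env <- new.env(parent = emptyenv())

#' Load the schema definition
#'
#' Reads the versioned schema asset (tables, columns, vocabularies,
#' key constraints) bundled with the package. Cached after first load.
#'
#' @return A list with elements `schema_version`, `vocabularies` and `tables`.
#' @export
gcdm_schema <- function() {
  if (is.null(.gcdm_env$schema)) {
    path <- system.file("extdata", "gcdm_schema.json", package = "gcdm",
                        mustWork = TRUE)
    .gcdm_env$schema <- jsonlite::read_json(path, simplifyVector = FALSE)
  }
  .gcdm_env$schema
}

schema_table <- function(name) {
  for (tbl in gcdm_schema()$tables) if (tbl$name == name) return(tbl)
  stop(sprintf("unknown table '%s'", name), call. = FALSE)
}

schema_table_names <- function() {
  vapply(gcdm_schema()$tables, `[[`, character(1), "name")
}

vocabulary <- function(name) {
  voc <- gcdm_schema()$vocabularies[[name]]
  if (is.null(voc)) stop(sprintf("unknown vocabulary '%s'", name), call. = FALSE)
  unlist(voc)
}

col_r_type <- function(col) {
  switch(col$type,
         integer = integer(),
         number = numeric(),
         text = ,
         date = character(),
         stop(sprintf("unknown column type '%s'", col$type), call. = FALSE))
}

empty_table <- function(tbl) {
  cols <- lapply(tbl$columns, col_r_type)
  names(cols) <- vapply(tbl$columns, `[[`, character(1), "name")
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Initialize an empty cohort database
#'
#' Creates a database holding all nine tables of the model with key and
#' vocabulary constraints active. The database lives in memory (handle
#' semantics: inserts mutate it in place); when `path` is given the handle
#' is bound to an on-disk directory that [db_save()] fills with one
#' tab-separated file per table plus a metadata marker.
#'
#' @param path Optional directory to bind the database to. Must not already
#'   contain a database unless `overwrite = TRUE`; a path holding anything
#'   other than a database produced by this package is refused.
#' @param overwrite Replace an existing database directory at `path`.
#' @return A `gcdm_db` handle.
#' @examples
#' db <- init_database()
#' db_row_counts(db)
#' @export
init_database <- function(path = NULL, overwrite = FALSE) {
  db <- structure(new.env(parent = emptyenv()), class = "gcdm_db")
  db$tables <- stats::setNames(
    lapply(gcdm_schema()$tables, empty_table), schema_table_names())
  db$schema_version <- gcdm_schema()$schema_version
  db$path <- path
  if (!is.null(path)) {
    if (file.exists(path) && !dir.exists(path))
      stop(sprintf("'%s' exists and is not a database directory", path),
           call. = FALSE)
    meta <- file.path(path, "gcdm_meta.json")
    if (dir.exists(path)) {
      entries <- list.files(path, all.files = TRUE, no.. = TRUE)
      if (length(entries) > 0 && !file.exists(meta))
        stop(sprintf("'%s' is non-empty and not a database directory", path),
             call. = FALSE)
      if (file.exists(meta) && !overwrite)
        stop(sprintf("database already initialized at '%s' (use overwrite = TRUE)",
                     path), call. = FALSE)
      unlink(file.path(path, entries), recursive = TRUE)
    } else {
      dir.create(path, recursive = TRUE)
    }
    db_save(db)
  }
  db
}

#' @export
print.gcdm_db <- function(x, ...) {
  cat(sprintf("<gcdm_db> schema %s%s\n", x$schema_version,
              if (is.null(x$path)) " (in-memory)" else paste0(" @ ", x$path)))
  counts <- db_row_counts(x)
  for (nm in names(counts)) cat(sprintf("  %-22s %d rows\n", nm, counts[[nm]]))
  invisible(x)
}

#' Fetch one table of a cohort database
#'
#' @param db A `gcdm_db` handle.
#' @param table Table name.
#' @return The table as a data frame.
#' @export
db_table <- function(db, table) {
  stopifnot(inherits(db, "gcdm_db"))
  if (!table %in% names(db$tables))
    stop(sprintf("unknown table '%s'", table), call. = FALSE)
  db$tables[[table]]
}

#' Row counts of every table
#'
#' @param db A `gcdm_db` handle.
#' @return Named integer vector of row counts.
#' @export
db_row_counts <- function(db) {
  stopifnot(inherits(db, "gcdm_db"))
  vapply(db$tables, nrow, integer(1))
}

# ---- row coercion and constraint checking -----------------------------------

coerce_column <- function(values, col, table, where = "insert_records") {
  if (is.factor(values)) values <- as.character(values)
  if (is.character(values)) values[!is.na(values) & values == ""] <- NA
  out <- switch(col$type,
    integer = {
      if (is.character(values)) {
        res <- suppressWarnings(as.integer(values))
        bad <- which(!is.na(values) & is.na(res))
        if (length(bad) > 0)
          stop_constraint(where, table, bad[1], col$name,
                          sprintf("not an integer: '%s'", values[bad[1]]))
        res
      } else if (is.numeric(values)) {
        bad <- which(!is.na(values) & values != floor(values))
        if (length(bad) > 0)
          stop_constraint(where, table, bad[1], col$name, "not an integer")
        as.integer(values)
      } else if (is.logical(values) && all(is.na(values))) {
        as.integer(values)
      } else stop_constraint(where, table, 1L, col$name, "not an integer column")
    },
    number = {
      if (is.character(values)) {
        res <- suppressWarnings(as.numeric(values))
        bad <- which(!is.na(values) & is.na(res))
        if (length(bad) > 0)
          stop_constraint(where, table, bad[1], col$name,
                          sprintf("not a number: '%s'", values[bad[1]]))
        res
      } else if (is.numeric(values)) as.numeric(values)
      else if (is.logical(values) && all(is.na(values))) as.numeric(values)
      else stop_constraint(where, table, 1L, col$name, "not a numeric column")
    },
    as.character(values))
  out
}

stop_constraint <- function(where, table, row, field, msg) {
  stop(structure(
    class = c("gcdm_constraint_error", "error", "condition"),
    list(message = sprintf("%s(%s): row %s, field '%s': %s",
                           where, table, row, field, msg),
         call = NULL, table = table, row = row, field = field)))
}

coerce_rows <- function(tbl, rows, where = "insert_records") {
  if (is.list(rows) && !is.data.frame(rows))
    rows <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r[!vapply(r, is.null, logical(1))],
                    stringsAsFactors = FALSE)))
  if (!is.data.frame(rows))
    stop("rows must be a data frame or a list of named lists", call. = FALSE)
  want <- vapply(tbl$columns, `[[`, character(1), "name")
  extra <- setdiff(names(rows), want)
  if (length(extra) > 0)
    stop(sprintf("%s(%s): unknown column(s): %s", where, tbl$name,
                 paste(extra, collapse = ", ")), call. = FALSE)
  out <- empty_table(tbl)[seq_len(nrow(rows)), , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_along(tbl$columns)) {
    col <- tbl$columns[[i]]
    vals <- if (col$name %in% names(rows)) rows[[col$name]] else
      rep(NA, nrow(rows))
    out[[col$name]] <- coerce_column(vals, col, tbl$name, where)
  }
  out
}

# Column-level checks (type/domain/vocabulary), vectorized; returns a
# violations data.frame with columns row, field, rule, message.
check_columns <- function(tbl, df) {
  v <- list()
  add <- function(rows, field, rule, message) {
    if (length(rows) > 0)
      v[[length(v) + 1]] <<- data.frame(row = rows, field = field,
                                        rule = rule, message = message,
                                        stringsAsFactors = FALSE)
  }
  for (col in tbl$columns) {
    x <- df[[col$name]]
    if (!isTRUE(col$nullable))
      add(which(is.na(x)), col$name, "not_null", "missing value")
    if (!is.null(col$vocabulary)) {
      voc <- vocabulary(col$vocabulary)
      bad <- which(!is.na(x) & !(x %in% voc))
      add(bad, col$name, "vocabulary",
          sprintf("'%s' not in {%s}", x[bad], paste(voc, collapse = ", ")))
    }
    if (!is.null(col$min)) {
      bad <- which(!is.na(x) & x < col$min)
      add(bad, col$name, "range", sprintf("value %s below %s", x[bad], col$min))
    }
    if (!is.null(col$max)) {
      bad <- which(!is.na(x) & x > col$max)
      add(bad, col$name, "range", sprintf("value %s above %s", x[bad], col$max))
    }
    if (identical(col$type, "date")) {
      bad <- which(!is.na(x) & !grepl("^\\d{4}-\\d{2}-\\d{2}$", x))
      add(bad, col$name, "format", "not an ISO-8601 date (YYYY-MM-DD)")
    }
  }
  if (tbl$name == "variant_occurrence") {
    both <- !is.na(df$genomic_start) & !is.na(df$genomic_end)
    bad <- which(both & df$genomic_end < df$genomic_start)
    add(bad, "genomic_end", "range", "genomic_end before genomic_start")
    hp <- df$hgvs_p
    for (i in which(!is.na(hp))) {
      err <- protein_hgvs_error(hp[i])
      if (!is.null(err))
        add(i, "hgvs_p", "hgvs_parse", sprintf("'%s': %s", hp[i], err))
    }
  }
  if (length(v) == 0)
    return(data.frame(row = integer(), field = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

# Referential checks of df (candidate rows of tbl) against the database;
# `df` may include rows not yet committed, so keys are checked against the
# union of existing and incoming rows where self-batch references make sense.
check_references <- function(tbl, df, db) {
  v <- list()
  add <- function(rows, field, rule, message) {
    if (length(rows) > 0)
      v[[length(v) + 1]] <<- data.frame(row = rows, field = field,
                                        rule = rule, message = message,
                                        stringsAsFactors = FALSE)
  }
  for (col in tbl$columns) {
    ref <- col$references
    if (is.null(ref)) next
    keys <- db$tables[[ref$table]][[ref$column]]
    x <- df[[col$name]]
    bad <- which(!is.na(x) & !(x %in% keys))
    add(bad, col$name, "foreign_key",
        sprintf("value %s not found in %s.%s", x[bad], ref$table, ref$column))
  }
  if (tbl$name == "variant_occurrence") {
    spec <- db$tables$specimen
    tgt_role <- spec$specimen_role[match(df$specimen_id_target, spec$specimen_id)]
    bad <- which(!is.na(df$specimen_id_target) & !is.na(tgt_role) &
                   tgt_role != "target")
    add(bad, "specimen_id_target", "specimen_role",
        "target specimen's role is not 'target'")
  }
  if (length(v) == 0)
    return(data.frame(row = integer(), field = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

check_keys <- function(tbl, df, db) {
  v <- list()
  add <- function(rows, field, rule, message) {
    if (length(rows) > 0)
      v[[length(v) + 1]] <<- data.frame(row = rows, field = field,
                                        rule = rule, message = message,
                                        stringsAsFactors = FALSE)
  }
  pk <- tbl$primary_key
  existing <- db$tables[[tbl$name]][[pk]]
  x <- df[[pk]]
  add(which(x %in% existing), pk, "duplicate_key", "key already present")
  add(which(duplicated(x)), pk, "duplicate_key", "key duplicated in batch")
  for (uq in tbl$unique %||% list()) {
    cols <- unlist(uq)
    key_new <- do.call(paste, c(df[cols], sep = "\r"))
    key_old <- do.call(paste, c(db$tables[[tbl$name]][cols], sep = "\r"))
    add(which(key_new %in% key_old | duplicated(key_new)),
        paste(cols, collapse = "+"), "unique",
        sprintf("duplicate (%s) combination", paste(cols, collapse = ", ")))
  }
  if (length(v) == 0)
    return(data.frame(row = integer(), field = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Insert rows into a table, all-or-nothing
#'
#' Validates every candidate row against the table's type, vocabulary,
#' key and foreign-key constraints before anything is committed; the first
#' violation aborts the whole batch with an error naming the offending row
#' index and field.
#'
#' @param db A `gcdm_db` handle.
#' @param table Table name.
#' @param rows Data frame (or list of named lists) conforming to the table.
#' @return Number of rows inserted, equal to `nrow(rows)`.
#' @export
insert_records <- function(db, table, rows) {
  stopifnot(inherits(db, "gcdm_db"))
  tbl <- schema_table(table)
  df <- coerce_rows(tbl, rows)
  if (nrow(df) == 0) return(0L)
  viol <- rbind(check_columns(tbl, df),
                check_keys(tbl, df, db),
                check_references(tbl, df, db))
  if (nrow(viol) > 0) {
    viol <- viol[order(viol$row), , drop = FALSE]
    stop_constraint("insert_records", table, viol$row[1], viol$field[1],
                    paste0("[", viol$rule[1], "] ", viol$message[1]))
  }
  db$tables[[table]] <- rbind(db$tables[[table]], df)
  nrow(df)
}

#' Validate a whole database
#'
#' Re-checks every invariant of the model over all nine tables: column
#' domains and vocabularies, primary-key and composite uniqueness,
#' referential integrity, specimen-role consistency, and protein-HGVS
#' re-parseability. Violations are data, not exceptions.
#'
#' @param db A `gcdm_db` handle.
#' @return Data frame with columns `table`, `row_key`, `rule`, `message`;
#'   zero rows iff the database is consistent. Ordering is deterministic
#'   (schema table order, then primary-key order).
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "gcdm_db"))
  out <- list()
  for (tbl in gcdm_schema()$tables) {
    df <- db$tables[[tbl$name]]
    if (nrow(df) == 0) next
    viol <- rbind(check_columns(tbl, df),
                  check_references(tbl, df, db))
    pk <- df[[tbl$primary_key]]
    dup <- which(duplicated(pk) | duplicated(pk, fromLast = TRUE))
    if (length(dup) > 0)
      viol <- rbind(viol, data.frame(row = dup, field = tbl$primary_key,
                                     rule = "duplicate_key",
                                     message = "primary key not unique",
                                     stringsAsFactors = FALSE))
    for (uq in tbl$unique %||% list()) {
      cols <- unlist(uq)
      key <- do.call(paste, c(df[cols], sep = "\r"))
      dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
      if (length(dup) > 0)
        viol <- rbind(viol, data.frame(row = dup,
                                       field = paste(cols, collapse = "+"),
                                       rule = "unique",
                                       message = "combination not unique",
                                       stringsAsFactors = FALSE))
    }
    if (nrow(viol) > 0) {
      viol <- viol[order(viol$row, viol$field), , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        table = tbl$name,
        row_key = as.character(pk[viol$row]),
        rule = paste0(viol$rule, ":", viol$field),
        message = viol$message,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(table = character(), row_key = character(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# ---- persistence ------------------------------------------------------------

#' Save a database as per-table TSV files
#'
#' Writes one UTF-8 tab-separated file per table (header row = column
#' names, empty string for missing values) plus a `gcdm_meta.json` marker
#' carrying the schema version. Output is byte-deterministic for a given
#' database state.
#'
#' @param db A `gcdm_db` handle.
#' @param path Directory; defaults to the path the handle was bound to.
#' @return `path`, invisibly.
#' @export
db_save <- function(db, path = db$path) {
  stopifnot(inherits(db, "gcdm_db"))
  if (is.null(path)) stop("no path bound to this database", call. = FALSE)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  jsonlite::write_json(
    list(schema_version = db$schema_version, tables = names(db$tables)),
    file.path(path, "gcdm_meta.json"), auto_unbox = TRUE, pretty = TRUE)
  for (nm in names(db$tables))
    utils::write.table(db$tables[[nm]], file.path(path, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Load a database saved with [db_save()]
#'
#' The reloaded database is re-validated; violations raise an error since a
#' dump produced by this package should always round-trip cleanly.
#'
#' @param path Directory holding `gcdm_meta.json` and per-table TSVs.
#' @return A `gcdm_db` handle bound to `path`.
#' @export
db_load <- function(path) {
  meta_path <- file.path(path, "gcdm_meta.json")
  if (!file.exists(meta_path))
    stop(sprintf("'%s' is not a database directory", path), call. = FALSE)
  db <- init_database()
  db$path <- path
  for (tbl in gcdm_schema()$tables) {
    f <- file.path(path, paste0(tbl$name, ".tsv"))
    if (!file.exists(f)) next
    raw <- utils::read.delim(f, colClasses = "character",
                             na.strings = "", check.names = FALSE)
    if (nrow(raw) == 0) next
    db$tables[[tbl$name]] <- coerce_rows(tbl, raw, where = "db_load")
  }
  viol <- validate_database(db)
  if (nrow(viol) > 0)
    stop(sprintf("loaded database has %d constraint violation(s); first: %s/%s %s",
                 nrow(viol), viol$table[1], viol$row_key[1], viol$message[1]),
         call. = FALSE)
  db
}

#' Pool several databases into one
#'
#' Concatenates the tables of databases that share the schema version.
#' Keys must be disjoint across inputs (the synthetic two-site generator
#' offsets site B's keys for this reason); the pooled database is validated.
#'
#' @param ... `gcdm_db` handles.
#' @return A new in-memory `gcdm_db`.
#' @export
db_pool <- function(...) {
  dbs <- list(...)
  stopifnot(length(dbs) >= 1, all(vapply(dbs, inherits, logical(1), "gcdm_db")))
  out <- init_database()
  for (nm in names(out$tables))
    out$tables[[nm]] <- do.call(rbind, lapply(dbs, function(d) d$tables[[nm]]))
  viol <- validate_database(out)
  if (nrow(viol) > 0)
    stop(sprintf("pooled database invalid (%d violations; key collision?)",
                 nrow(viol)), call. = FALSE)
  out
}
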