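# A deliberately narrow SQL evaluator over in-memory data frames, covering
# exactly the SELECT dialect the treatment-record TagMap uses:
#
#   SELECT col[, col ...] FROM Table [Alias]
#     [INNER JOIN Table2 Alias2 ON cond [AND cond ...]]
#     [WHERE cond [AND cond ...]]
#
# where a condition is `ref = ?`, `ref = ref`, or a bare column reference
# (shorthand for an equi-join on the same-named column of the two joined
# tables).  `?` placeholders bind positionally in order of appearance
# (ON before WHERE).  Anything else fails loudly.

strip_ws <- function(s) gsub("^\\s+|\\s+$", "", s)

parse_sql_select <- function(query) {
  q <- strip_ws(gsub("\\s+", " ", query))
  m <- regexec(
    "^SELECT (.+?) FROM ([A-Za-z_][A-Za-z0-9_]*)( [A-Za-z_][A-Za-z0-9_]*)?( INNER JOIN ([A-Za-z_][A-Za-z0-9_]*)( [A-Za-z_][A-Za-z0-9_]*)? ON (.+?))?( WHERE (.+))?$",
    q, ignore.case = TRUE)
  g <- regmatches(q, m)[[1]]
  if (length(g) == 0) stop("unsupported SQL statement: ", query)
  cols <- strip_ws(strsplit(g[2], ",")[[1]])
  list(cols = cols,
       table = g[3], alias = strip_ws(g[4]),
       join_table = if (nzchar(g[6])) g[6] else NULL,
       join_alias = strip_ws(g[7]),
       on = if (nzchar(g[8])) strip_ws(strsplit(g[8], " AND ", fixed = FALSE)[[1]]) else character(0),
       where = if (nzchar(g[10])) strip_ws(strsplit(g[10], "(?i) AND ", perl = TRUE)[[1]]) else character(0))
}

#' SQL query backend over CSV-backed tables
#'
#' @param tables Named list of data frames, or a directory containing
#'   `<Table>.csv` files.
#' @return A `query_backend` of kind `"SQL"`.
#' @export
sql_backend <- function(tables) {
  if (is.character(tables)) {
    files <- list.files(tables, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0) stop("no CSV tables found in ", tables)
    nm <- sub("\\.csv$", "", basename(files))
    tables <- stats::setNames(
      lapply(files, utils::read.csv, stringsAsFactors = FALSE,
             colClasses = "character"), nm)
  }
  structure(list(kind = "SQL", tables = tables), class = "query_backend")
}

resolve_colref <- function(ref, env) {
  # env: named list alias/table-name (lowercased) -> data.frame (filtered rows)
  parts <- strsplit(ref, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2) {
    tab <- env[[tolower(parts[1])]]
    if (is.null(tab)) stop("unknown table or alias '", parts[1], "' in SQL query")
    if (!parts[2] %in% names(tab)) stop("unknown column ", ref)
    return(tab[[parts[2]]])
  }
  hits <- Filter(function(t) parts[1] %in% names(t), env)
  if (length(hits) == 0) stop("unknown column ", ref)
  hits[[1]][[parts[1]]]
}

is_colref <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_]*(\\.[A-Za-z_][A-Za-z0-9_]*)?$", x)

#' Evaluate a SQL query against a backend
#'
#' Placeholders (`?`) bind positionally from `bindings`; the number of
#' placeholders must equal `length(bindings)`.  Returns the selected
#' columns as a data frame (one element per row/column); callers apply the
#' VR concatenation rules.
#'
#' @param query SQL text (see package vignette for the supported subset).
#' @param bindings Ordered values for the `?` placeholders.
#' @param backend A [sql_backend()].
#' @export
evaluate_sql <- function(query, bindings, backend) {
  stopifnot(inherits(backend, "query_backend"), backend$kind == "SQL")
  n_ph <- lengths(regmatches(query, gregexpr("?", query, fixed = TRUE)))
  if (n_ph != length(bindings))
    stop("binding count mismatch: query has ", n_ph, " placeholder(s), ",
         length(bindings), " value(s) supplied")
  p <- parse_sql_select(query)
  get_table <- function(name) {
    t <- backend$tables[[name]]
    if (is.null(t)) stop("unknown table: ", name)
    t
  }
  t1 <- get_table(p$table)
  env <- list()
  env[[tolower(p$table)]] <- t1
  if (nzchar(p$alias)) env[[tolower(p$alias)]] <- t1
  rows <- t1
  binding_i <- 0L
  next_binding <- function() {
    binding_i <<- binding_i + 1L
    as.character(bindings[[binding_i]])
  }
  apply_conditions <- function(rows, conds, env, frames) {
    for (cond in conds) {
      if (grepl("=", cond, fixed = TRUE)) {
        sides <- strip_ws(strsplit(cond, "=", fixed = TRUE)[[1]])
        if (length(sides) != 2) stop("unsupported condition: ", cond)
        lhs <- resolve_colref(sides[1], env)
        rhs <- if (sides[2] == "?") next_binding()
               else if (is_colref(sides[2])) resolve_colref(sides[2], env)
               else gsub("^'|'$", "", sides[2])
        keep <- lhs == rhs
      } else if (is_colref(cond)) {
        # bare reference: equi-join on the same-named column of the two
        # distinct joined tables
        col <- sub("^.*\\.", "", cond)
        vals <- lapply(frames, function(t)
          if (col %in% names(t)) t[[col]] else NULL)
        vals <- Filter(Negate(is.null), vals)
        if (length(vals) < 2)
          stop("bare join condition '", cond,
               "' needs the column in both tables")
        keep <- vals[[1]] == vals[[2]]
      } else stop("unsupported condition: ", cond)
      keep <- keep & !is.na(keep)
      rows <- rows[keep, , drop = FALSE]
      env <- lapply(env, function(t) t[keep, , drop = FALSE])
      frames <- lapply(frames, function(t) t[keep, , drop = FALSE])
    }
    list(rows = rows, env = env, frames = frames)
  }
  frames <- list(rows)
  if (!is.null(p$join_table)) {
    t2 <- get_table(p$join_table)
    # cross product, then ON conditions filter it
    i1 <- rep(seq_len(nrow(rows)), each = max(nrow(t2), 1L))
    i2 <- rep(seq_len(max(nrow(t2), 1L)), times = nrow(rows))
    if (nrow(t2) == 0) { i1 <- integer(0); i2 <- integer(0) }
    rows <- rows[i1, , drop = FALSE]
    t2x <- t2[i2, , drop = FALSE]
    env <- list()
    env[[tolower(p$table)]] <- rows
    if (nzchar(p$alias)) env[[tolower(p$alias)]] <- rows
    env[[tolower(p$join_table)]] <- t2x
    if (nzchar(p$join_alias)) env[[tolower(p$join_alias)]] <- t2x
    frames <- list(rows, t2x)
    res <- apply_conditions(rows, p$on, env, frames)
    rows <- res$rows; env <- res$env; frames <- res$frames
  }
  res <- apply_conditions(rows, p$where, env, frames)
  rows <- res$rows; env <- res$env
  out <- lapply(p$cols, function(col) resolve_colref(col, env))
  names(out) <- sub("^.*\\.", "", p$cols)
  as.data.frame(out, stringsAsFactors = FALSE)
}
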