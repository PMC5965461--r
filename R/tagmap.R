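# TagMap parsing and evaluation: the declarative core.  A TagMap is an XML
# file listing, for one DICOM-RT object type, every tag with either a
# literal value or a query into the vendor storage.  The engine builds a
# query-bearing DICOM skeleton, then evaluates the queries in document
# order against a pluggable backend (XPath over the patient master XML, or
# the SQL subset over relational fixtures), so later queries can bind
# values resolved by earlier ones.

.target_types <- c("CT", "MVCT", "RTPLAN", "RTDOSE", "RTSTRUCT", "QADOSE",
                   "DELIVERY_SINOGRAM", "RTRECORD")

#' Parse a TagMap XML document
#'
#' The dialect: root `<dicom target="..." [versions="..."] [backend="..."]>`
#' containing `<attr tag="GGGGEEEE" [vr="XX"] [src="literal|query"]
#' [count="query"] [params="src1,src2"]>payload</attr>` elements; a
#' sequence (`vr="SQ"`) wraps exactly one `<item>` holding the template for
#' all generated items.  A payload is classified as a query when it starts
#' with `SELECT ` or contains `/` or starts with `$` or `(`; the explicit
#' `src` attribute overrides the heuristic.  Param sources are
#' `input:<name>` (from the binding context) or `tag:GGGGEEEE` (a value
#' resolved earlier in document order).
#'
#' @param x TagMap XML text or a file path.
#' @return A `tagmap` object.
#' @export
parse_tagmap <- function(x) {
  doc <- if (length(x) == 1 && file.exists(x)) xml2::read_xml(x)
         else xml2::read_xml(paste(x, collapse = "\n"))
  root <- xml2::xml_name(doc)
  if (root != "dicom") stop("TagMap root element must be <dicom>, got <", root, ">")
  target <- xml2::xml_attr(doc, "target")
  if (is.na(target)) target <- "RTRECORD"
  target <- match.arg(target, .target_types)
  versions <- xml2::xml_attr(doc, "versions")
  versions <- if (is.na(versions)) .version_labels
              else strsplit(versions, "\\s+")[[1]]
  backend_hint <- xml2::xml_attr(doc, "backend")
  entries <- parse_entries(doc)
  structure(list(target_type = target, version_scope = versions,
                 backend_hint = if (is.na(backend_hint)) NULL else backend_hint,
                 entries = entries), class = "tagmap")
}

classify_payload <- function(payload, src) {
  if (!is.na(src)) {
    if (!src %in% c("literal", "query")) stop("invalid src attribute: ", src)
    return(src == "query")
  }
  startsWith(payload, "SELECT ") || grepl("/", payload, fixed = TRUE) ||
    startsWith(payload, "$") || startsWith(payload, "(")
}

parse_entries <- function(node) {
  attrs <- xml2::xml_find_all(node, "attr")
  entries <- list()
  seen <- character(0)
  for (a in attrs) {
    tag <- xml2::xml_attr(a, "tag")
    tag <- tryCatch(canon_tag(tag),
                    error = function(e) stop("TagMap parse error: ",
                                             conditionMessage(e)))
    if (tag %in% seen)
      stop("TagMap parse error: duplicate tag ", tag, " at one nesting level")
    seen <- c(seen, tag)
    vr <- xml2::xml_attr(a, "vr")
    vr <- if (is.na(vr)) dcm_vr_for_tag(tag) else strip_ws(vr)
    if (is.na(vr)) stop("TagMap parse error: no VR for tag ", tag,
                        " (not in dictionary; add a vr attribute)")
    items <- xml2::xml_find_all(a, "item")
    if (identical(vr, "SQ")) {
      if (length(items) != 1)
        stop("TagMap parse error: sequence ", tag, " must contain exactly ",
             "one <item> template, found ", length(items))
      children <- parse_entries(items[[1]])
      count_src <- xml2::xml_attr(a, "count")
      entries[[length(entries) + 1L]] <- list(
        tag = tag, vr = "SQ", payload = NULL, is_query = FALSE,
        children = children,
        count_source = if (is.na(count_src)) NULL else count_src,
        params = parse_params(xml2::xml_attr(a, "params")))
      next
    }
    if (length(items) > 0)
      stop("TagMap parse error: <item> under non-SQ tag ", tag)
    payload <- strip_ws(xml2::xml_text(a))
    entries[[length(entries) + 1L]] <- list(
      tag = tag, vr = vr, payload = payload,
      is_query = classify_payload(payload, xml2::xml_attr(a, "src")),
      children = NULL, count_source = NULL,
      params = parse_params(xml2::xml_attr(a, "params")))
  }
  entries
}

parse_params <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  strip_ws(strsplit(s, ",")[[1]])
}

#' @export
print.tagmap <- function(x, ...) {
  cat("<tagmap> target ", x$target_type, ", ", length(x$entries),
      " top-level entries, versions ", paste(x$version_scope, collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Build the query-bearing DICOM skeleton of a TagMap
#'
#' Literal payloads are coerced to their VR and final; query payloads
#' become `tm_query` placeholders and sequences become `tm_sequence`
#' placeholders holding the single item template — the intermediate state
#' in which the DICOM object still "contains the queries".
#'
#' @param tagmap A [parse_tagmap()] result.
#' @return A `dicom_dataset` with placeholder values.
#' @export
build_skeleton <- function(tagmap) {
  skeleton_from_entries(tagmap$entries)
}

skeleton_from_entries <- function(entries) {
  ds <- dcm_dataset()
  for (e in entries) {
    value <- if (identical(e$vr, "SQ")) {
      structure(list(entry = e), class = "tm_sequence")
    } else if (e$is_query) {
      structure(list(query = e$payload, params = e$params), class = "tm_query")
    } else {
      coerce_vr(e$payload, e$vr, e$tag)
    }
    ds$elements[[e$tag]] <- list(vr = e$vr, value = value)
  }
  ds
}

is_placeholder <- function(v) inherits(v, "tm_query") || inherits(v, "tm_sequence")

#' Expand a sequence template into n items
#'
#' Each item is a deep copy of the one-item template with the 1-based item
#' index substituted for the `$i` variable in its queries.
#'
#' @param entry A sequence TagEntry (from a parsed `tagmap`).
#' @param count Non-negative number of items.
#' @return List of `count` entry lists.
#' @export
expand_sequence <- function(entry, count) {
  if (is.na(count) || count < 0) stop("sequence ", entry$tag,
                                      ": negative or invalid item count ", count)
  lapply(seq_len(count), function(i) {
    lapply(entry$children, function(ch) {
      if (!is.null(ch$payload) && ch$is_query)
        ch$payload <- gsub("$i", as.character(i), ch$payload, fixed = TRUE)
      ch
    })
  })
}

#' XPath query backend over one patient's master document
#'
#' Queries are evaluated against the patient's `patient.xml`.  Before
#' evaluation, `$<name>` variables are substituted from the binding
#' context's user inputs (and `$i` from the sequence item index).  A query
#' result that names a binary payload UID is marked for raw-data
#' attachment by the object builders.
#'
#' @param archive A `vendor_archive`.
#' @param patient_id Which patient document to query.
#' @export
xpath_backend <- function(archive, patient_id) {
  structure(list(kind = "XPATH", archive = archive, patient_id = patient_id),
            class = "query_backend")
}

#' Binding context for TagMap evaluation
#'
#' @param user_inputs Named list of user-supplied selectors (patient ID,
#'   scan UID, fraction number, ...).
#' @export
binding_context <- function(user_inputs = list()) {
  structure(list(user_inputs = user_inputs,
                 resolved = new.env(parent = emptyenv())),
            class = "binding_context")
}

substitute_vars <- function(query, ctx, item_index = NULL) {
  if (!is.null(item_index))
    query <- gsub("$i", as.character(item_index), query, fixed = TRUE)
  for (nm in names(ctx$user_inputs))
    query <- gsub(paste0("$", nm), as.character(ctx$user_inputs[[nm]]),
                  query, fixed = TRUE)
  query
}

backend_eval <- function(backend, query, ctx, params, tag, item_index = NULL) {
  if (backend$kind == "XPATH") {
    q <- substitute_vars(query, ctx, item_index)
    if (grepl("^\\s*count\\(", q)) {
      doc <- patient_doc(backend$archive, backend$patient_id)
      return(xml2::xml_find_num(doc, q))
    }
    doc <- patient_doc(backend$archive, backend$patient_id)
    nodes <- tryCatch(xml2::xml_find_all(doc, q),
                      error = function(e) stop("XPath error at tag ", tag, ": ",
                                               conditionMessage(e)))
    return(xml2::xml_text(nodes))
  }
  if (backend$kind == "SQL") {
    bindings <- lapply(params, function(p) {
      if (startsWith(p, "input:")) {
        nm <- sub("^input:", "", p)
        val <- ctx$user_inputs[[nm]]
        if (is.null(val)) stop("no user input named '", nm, "' for tag ", tag)
        val
      } else if (startsWith(p, "tag:")) {
        src <- canon_tag(sub("^tag:", "", p))
        if (!exists(src, envir = ctx$resolved))
          stop(structure(class = c("tm_unresolved", "error", "condition"),
                         list(message = paste0("tag ", tag,
                           " binds unresolved tag ", src,
                           " (staged evaluation reads earlier entries only)"),
                           call = NULL, missing_tag = src)))
        get(src, envir = ctx$resolved)
      } else stop("invalid param source '", p, "' for tag ", tag)
    })
    q <- if (!is.null(item_index)) gsub("$i", as.character(item_index),
                                        query, fixed = TRUE) else query
    rows <- evaluate_sql(q, bindings, backend)
    if (nrow(rows) > 1)
      stop("query for tag ", tag, " returned ", nrow(rows),
           " rows where a single value was expected")
    if (nrow(rows) == 0) return(character(0))
    return(as.character(unlist(rows[1, ], use.names = FALSE)))
  }
  stop("unknown backend kind: ", backend$kind)
}

# VR coercion of raw query results; multi-column PN joins components in
# reverse column order (FIRST, LAST -> "LAST^FIRST"); other VRs treat
# multiple values as a DICOM multi-value.  Whitespace-separated numeric
# payloads (tomo-lite vector elements) split into multi-values; ISO-8601
# timestamps convert to DA/TM/DT on the fly.
coerce_vr <- function(values, vr, tag) {
  values <- as.character(values)
  if (vr %in% c("DS", "IS", "US", "UL", "FL", "FD") && length(values) == 1 &&
      grepl("\\s", strip_ws(values)))
    values <- strsplit(strip_ws(values), "\\s+")[[1]]
  is_iso <- function(v) grepl("^\\d{4}-\\d{2}-\\d{2}", v)
  out <- tryCatch({
    switch(vr,
      PN = if (length(values) > 1) paste(rev(values), collapse = "^") else values,
      DA = if (all(is_iso(values))) iso_to_da(values) else values,
      TM = if (all(is_iso(values))) iso_to_tm(values) else values,
      DT = if (all(is_iso(values))) iso_to_dt(values) else values,
      DS = { v <- as.numeric(values); if (anyNA(v)) stop("not numeric"); format_ds(v) },
      IS = { v <- suppressWarnings(as.integer(values)); if (anyNA(v)) stop("not an integer"); as.character(v) },
      US = , UL = { v <- suppressWarnings(as.numeric(values)); if (anyNA(v) || any(v < 0)) stop("not a non-negative integer"); v },
      FL = , FD = { v <- suppressWarnings(as.numeric(values)); if (anyNA(v)) stop("not numeric"); v },
      UI = { if (length(values) && !all(vapply(values, is_valid_uid, TRUE))) stop("not a valid UID"); values },
      values)
  }, error = function(e)
    stop("VR coercion failure at tag ", tag, " (VR ", vr, "): raw value '",
         paste(values, collapse = "\\"), "': ", conditionMessage(e)))
  out
}

#' Evaluate a DICOM skeleton against a backend
#'
#' Walks the skeleton strictly in document order, replacing each query
#' placeholder by its evaluated, VR-coerced value; values resolved earlier
#' are available to later queries through `tag:` param sources (SQL) or
#' `$` variables (XPath).  Sequences evaluate their item count, expand the
#' template with `$i` bound, and recurse.  An empty result for a
#' mandatory (Type-1) tag of the target type records an element failure
#' and flags the dataset `INCOMPLETE`; optional tags degrade to a logged
#' warning.  Query results naming a binary payload UID are annotated for
#' raw-data attachment.
#'
#' @param skeleton Dataset from [build_skeleton()].
#' @param backend An [xpath_backend()] or [sql_backend()].
#' @param ctx A [binding_context()].
#' @param target_type Object type (for the mandatory-tag table).
#' @return The evaluated dataset, with attributes `completeness`
#'   (`"COMPLETE"` or `"INCOMPLETE"`) and `failures` (character).
#' @export
evaluate <- function(skeleton, backend, ctx = binding_context(),
                     target_type = "RTRECORD") {
  failures <- character(0)
  ds <- skeleton
  blob_uids <- if (!is.null(backend$archive)) backend$archive$binary_index$uid
               else character(0)
  type1 <- mandatory_tags(target_type)
  for (tag in names(ds$elements)) {
    el <- ds$elements[[tag]]
    if (inherits(el$value, "tm_sequence")) {
      entry <- el$value$entry
      count <- if (is.null(entry$count_source)) 1 else {
        cnt <- backend_eval(backend, entry$count_source, ctx,
                            entry$params, tag)
        as.numeric(cnt[1])
      }
      if (is.na(count) || count < 0)
        stop("sequence ", tag, ": count query yielded ", count)
      item_templates <- expand_sequence(entry, count)
      items <- lapply(seq_along(item_templates), function(i) {
        sk <- skeleton_from_entries(item_templates[[i]])
        ev <- evaluate_item(sk, backend, ctx, i, blob_uids, failures)
        failures <<- c(failures, attr(ev, "failures"))
        ev
      })
      ds$elements[[tag]] <- list(vr = "SQ", value = items)
      next
    }
    if (!inherits(el$value, "tm_query")) next
    # a binding on a tag that itself failed propagates incompleteness
    # downstream instead of aborting the object
    res <- tryCatch(
      backend_eval(backend, el$value$query, ctx, el$value$params, tag),
      tm_unresolved = function(e) {
        if (e$missing_tag %in% failures) character(0) else stop(e)
      })
    if (length(res) == 0 || all(!nzchar(res))) {
      if (tag %in% type1) {
        failures <- c(failures, tag)
        ds$elements[[tag]] <- list(vr = el$vr, value = character(0))
      } else {
        message("evaluate: empty result for optional tag ", tag)
        ds$elements[[tag]] <- NULL
      }
      next
    }
    val <- coerce_vr(res, el$vr, tag)
    if (length(val) == 1 && val %in% blob_uids)
      attr(val, "blob_uid") <- as.character(val)
    ds$elements[[tag]] <- list(vr = el$vr, value = val)
    assign(tag, val, envir = ctx$resolved)
  }
  attr(ds, "completeness") <- if (length(failures)) "INCOMPLETE" else "COMPLETE"
  attr(ds, "failures") <- failures
  ds
}

evaluate_item <- function(sk, backend, ctx, item_index, blob_uids,
                          parent_failures = character(0)) {
  failures <- character(0)
  for (tag in names(sk$elements)) {
    el <- sk$elements[[tag]]
    if (!inherits(el$value, "tm_query")) next
    res <- tryCatch(
      backend_eval(backend, el$value$query, ctx, el$value$params, tag,
                   item_index = item_index),
      tm_unresolved = function(e) {
        if (e$missing_tag %in% c(parent_failures, failures)) character(0)
        else stop(e)
      })
    if (length(res) == 0 || all(!nzchar(res))) {
      failures <- c(failures, tag)
      sk$elements[[tag]] <- list(vr = el$vr, value = character(0))
      next
    }
    val <- coerce_vr(res, el$vr, tag)
    if (length(val) == 1 && val %in% blob_uids)
      attr(val, "blob_uid") <- as.character(val)
    sk$elements[[tag]] <- list(vr = el$vr, value = val)
  }
  attr(sk, "failures") <- failures
  sk
}
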