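#' Default cost table
#'
#' Maps each integer symbol to its own numeric value, the natural "price
#' table" for expression levels: aggregates like `avg(pattern) <= 0` then read
#' directly as statements about expression.
#'
#' @param alphabet integer symbols.
#' @return named numeric vector (names are symbols as strings).
#' @export
default_cost_table <- function(alphabet) {
  setNames(as.numeric(alphabet), as.character(alphabet))
}

CONSTRAINT_AGGS <- c("min", "max", "range", "sum", "avg", "countVal", "length")
CONSTRAINT_TARGETS <- c("pattern", "items", "rows", "cols")
CONSTRAINT_RELS <- c("contains", "superset", "excludes")

#' Parse constraint expressions
#'
#' Grammar (one constraint per line, `#` starts a comment):
#' ```
#' atom := AGG '(' TARGET ')' CMP NUMBER
#'       | TARGET REL '{' id (',' id)* '}'
#'       | 'regex' '(' SEQPATTERN ')'
#' AGG  := min|max|range|sum|avg|countVal|length
#' TARGET := pattern|items|rows|cols ; CMP := <=|>=|=
#' REL  := contains|superset|excludes
#' expr := atom (('and'|'or') atom)*
#' ```
#' `SEQPATTERN` uses column ids, `<` for precedence, `(..)` for co-occurrence
#' and `*` as a wildcard, e.g. `regex(y2 < (y1 y3) < *)`.
#'
#' Targets: `pattern` is the original symbol pattern, `items` the mined
#' column-symbol items, `rows` the coverage and `cols` the column set.
#'
#' @param text a single constraint expression.
#' @return object of class `bic_constraint` (atoms joined by and/or).
#' @export
parse_constraint <- function(text) {
  src <- text
  text <- sub("#.*$", "", text)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty constraint expression")
  # split on and/or connectors (operand sets must not contain bare and/or ids)
  tokens <- strsplit(text, "\\s+(and|or)\\s+", perl = TRUE)[[1L]]
  ops <- regmatches(text, gregexpr("\\s+(and|or)\\s+", text))[[1L]]
  ops <- trimws(ops)
  if (length(ops) != length(tokens) - 1L) {
    stop("syntax error in constraint near position ",
         regexpr("and|or", text), ": ", src)
  }
  atoms <- lapply(tokens, parse_constraint_atom)
  structure(list(atoms = atoms, ops = ops, text = src), class = "bic_constraint")
}

parse_constraint_atom <- function(text) {
  text <- trimws(text)
  m <- regmatches(text, regexec("^regex\\s*\\((.*)\\)$", text))[[1L]]
  if (length(m)) {
    return(structure(list(kind = "regex", tokens = parse_seqpattern(m[2L]), text = text),
                     class = "bic_atom"))
  }
  m <- regmatches(text, regexec(
    "^([A-Za-z]+)\\s*\\(\\s*([A-Za-z]+)\\s*\\)\\s*(<=|>=|==|=)\\s*(-?[0-9.]+)$", text))[[1L]]
  if (length(m)) {
    agg <- m[2L]; target <- m[3L]
    if (!agg %in% CONSTRAINT_AGGS) stop("unknown aggregate '", agg, "' in: ", text)
    if (!target %in% CONSTRAINT_TARGETS) stop("unknown target '", target, "' in: ", text)
    cmp <- if (m[4L] == "==") "=" else m[4L]
    return(structure(list(kind = "aggregate", agg = agg, target = target,
                          cmp = cmp, value = as.numeric(m[5L]), text = text),
                     class = "bic_atom"))
  }
  m <- regmatches(text, regexec(
    "^([A-Za-z]+)\\s+(contains|superset|excludes)\\s+\\{\\s*([^}]*)\\s*\\}$", text))[[1L]]
  if (length(m)) {
    target <- m[2L]
    if (!target %in% CONSTRAINT_TARGETS) stop("unknown target '", target, "' in: ", text)
    ids <- trimws(strsplit(m[4L], ",", fixed = TRUE)[[1L]])
    ids <- ids[nzchar(ids)]
    if (!length(ids)) stop("empty operand set in: ", text)
    return(structure(list(kind = "set", target = target, rel = m[3L], set = ids, text = text),
                     class = "bic_atom"))
  }
  stop("syntax error at position 1 of constraint atom: '", text, "'")
}

parse_seqpattern <- function(text) {
  parts <- trimws(strsplit(text, "<", fixed = TRUE)[[1L]])
  lapply(parts, function(p) {
    if (p == "*") return("*")
    p <- gsub("[()]", " ", p)
    ids <- strsplit(trimws(p), "\\s+")[[1L]]
    if (!length(ids)) stop("empty itemset in sequence pattern")
    sort(ids)
  })
}

#' Parse a constraints file
#'
#' One constraint per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return list of `bic_constraint` objects.
#' @export
read_constraints <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    c_ <- tryCatch(parse_constraint(ln),
                   error = function(e) stop("constraint file line ", i, ": ", conditionMessage(e)))
    out[[length(out) + 1L]] <- c_
  }
  out
}

#' @export
print.bic_constraint <- function(x, ...) {
  cat("<constraint>", x$text, "\n")
  invisible(x)
}

#' Classify the pruning properties of a constraint
#'
#' Properties follow the standard pattern-mining taxonomy: monotone
#' constraints stay satisfied under pattern supersets, anti-monotone stay
#' violated, succinct constraints reduce to membership tests on
#' required/forbidden items, convertible constraints become prefix-checkable
#' under a cost-sorted enumeration, and regular expressions are
#' prefix-monotone. Unknown combinations classify as `"none"` and are handled
#' by post-filtering.
#'
#' Conjunctions are classified per conjunct (union of properties, each
#' conjunct pushed independently); a disjunction stays `"succinct"` only when
#' every atom is succinct, otherwise `"none"`.
#'
#' @param x a `bic_constraint` or single atom.
#' @param costs optional cost table; sum-constraints are only (anti-)monotone
#'   when costs are non-negative, so the table sharpens classification.
#' @return character vector of properties.
#' @export
classify_constraint <- function(x, costs = NULL) {
  if (inherits(x, "bic_atom")) return(classify_atom(x, costs))
  stopifnot(inherits(x, "bic_constraint"))
  if (length(x$atoms) == 1L) return(classify_atom(x$atoms[[1L]], costs))
  per_atom <- lapply(x$atoms, classify_atom, costs = costs)
  if (any(x$ops == "or")) {
    if (all(vapply(per_atom, function(p) "succinct" %in% p, logical(1)))) return("succinct")
    return("none")
  }
  props <- sort(unique(unlist(per_atom)))
  setdiff(props, if (length(props) > 1L) "none" else character(0))
}

classify_atom <- function(a, costs = NULL) {
  if (a$kind == "regex") return("prefix_monotone")
  if (a$kind == "set") {
    return(switch(a$target,
      rows = switch(a$rel,
        contains = "anti_monotone", superset = "anti_monotone", excludes = "monotone"),
      switch(a$rel,
        contains = c("succinct", "monotone"),
        superset = c("succinct", "monotone"),
        contains_all_cols = c("succinct", "monotone"),
        excludes = c("succinct", "anti_monotone"))
    ))
  }
  # aggregate atom
  nonneg <- is.null(costs) || all(costs >= 0, na.rm = TRUE)
  if (a$target == "rows") {
    if (a$agg == "length") {
      return(switch(a$cmp, ">=" = "anti_monotone", "<=" = "monotone", "none"))
    }
    return("none")
  }
  key <- paste0(a$agg, a$cmp)
  switch(key,
    "min<=" = c("succinct", "monotone"),
    "min>=" = "anti_monotone",
    "min=" = "succinct",
    "max>=" = c("succinct", "monotone"),
    "max<=" = "anti_monotone",
    "max=" = "succinct",
    "range>=" = "monotone",
    "range<=" = "anti_monotone",
    "sum<=" = if (nonneg) "anti_monotone" else "none",
    "sum>=" = if (nonneg) "monotone" else "none",
    "countVal>=" = "monotone",
    "countVal<=" = "anti_monotone",
    "length>=" = "monotone",
    "length<=" = "anti_monotone",
    "avg>=" = "convertible_am",
    "avg<=" = "convertible_am",
    "none"
  )
}

# ---- evaluation ------------------------------------------------------------

# Resolve the numeric cost of each item: explicit item entry in the cost table,
# else the symbol part's entry, else the symbol's numeric value. Annotation
# items have no cost (NA) and are excluded from aggregates.
item_costs <- function(items, costs = NULL) {
  out <- rep(NA_real_, length(items))
  ann <- is_annotation_item(items)
  if (!is.null(costs) && !is.null(names(costs))) {
    hit <- match(items, names(costs))
    out[!is.na(hit)] <- costs[hit[!is.na(hit)]]
  }
  need <- is.na(out) & !ann
  if (any(need)) {
    sym <- split_items(items[need])$symbol
    if (!is.null(costs) && !is.null(names(costs))) {
      hit <- match(sym, names(costs))
      found <- !is.na(hit)
      out[need][found] <- costs[hit[found]]
      sym_num <- suppressWarnings(as.numeric(sym))
      out[need][!found] <- sym_num[!found]
    } else {
      out[need] <- suppressWarnings(as.numeric(sym))
    }
  }
  if (any(is.na(out) & !ann)) {
    stop("no cost for item(s): ", paste(items[is.na(out) & !ann], collapse = ", "))
  }
  out
}

apply_agg <- function(agg, values) {
  if (!length(values)) return(NA_real_)
  switch(agg,
    min = min(values), max = max(values), range = max(values) - min(values),
    sum = sum(values), avg = mean(values),
    countVal = length(unique(values)), length = length(values))
}

cmp_ok <- function(x, cmp, v) {
  if (is.na(x)) return(FALSE)
  switch(cmp, "<=" = x <= v, ">=" = x >= v, "=" = isTRUE(all.equal(x, v)))
}

atom_target_set <- function(a, fp) {
  switch(a$target,
    pattern = as.character(fp$symbols),
    items = fp$items,
    rows = fp$rows,
    cols = fp$cols)
}

evaluate_atom <- function(a, fp, costs = NULL) {
  if (a$kind == "regex") {
    if (is.null(fp$groups)) stop("regex constraints apply to sequential patterns only")
    return(regex_full_match(a$tokens, fp$groups))
  }
  if (a$kind == "set") {
    tgt <- atom_target_set(a, fp)
    return(switch(a$rel,
      contains = length(intersect(a$set, tgt)) > 0L,
      superset = all(a$set %in% tgt),
      contains_all_cols = {
        by_col <- split(a$set, split_items(a$set)$col)
        all(vapply(by_col, function(g) any(g %in% tgt), logical(1)))
      },
      excludes = length(intersect(a$set, tgt)) == 0L))
  }
  # aggregate
  if (a$target == "rows") {
    if (a$agg != "length") stop("only length() is defined over rows")
    return(cmp_ok(length(fp$rows), a$cmp, a$value))
  }
  if (a$target == "cols") {
    if (a$agg != "length") stop("only length() is defined over cols")
    return(cmp_ok(length(fp$cols), a$cmp, a$value))
  }
  members <- if (a$target == "pattern") as.character(fp$symbols) else
    fp$items[!is_annotation_item(fp$items)]
  if (a$agg == "length") return(cmp_ok(length(members), a$cmp, a$value))
  cmp_ok(apply_agg(a$agg, item_costs(members, costs)), a$cmp, a$value)
}

#' Evaluate a constraint against a full-pattern or bicluster
#'
#' Aggregates are computed over the cost of the pattern's symbols (value items
#' only; annotation items never enter aggregates); set relations are
#' subset/intersection tests on the targeted component.
#'
#' @param constraint a `bic_constraint`.
#' @param fp a `full_pattern` (see [mine_closed()]) or a [bicluster()].
#' @param costs optional cost table (default: symbol value).
#' @return logical.
#' @export
evaluate_constraint <- function(constraint, fp, costs = NULL) {
  if (inherits(fp, "bicluster")) fp <- as_full_pattern(fp)
  stopifnot(inherits(constraint, "bic_constraint"))
  vals <- vapply(constraint$atoms, evaluate_atom, logical(1), fp = fp, costs = costs)
  out <- vals[1L]
  for (i in seq_along(constraint$ops)) {
    out <- if (constraint$ops[i] == "and") out && vals[i + 1L] else out || vals[i + 1L]
  }
  out
}

#' Translate pattern- or column-space constraints into item space
#'
#' A symbol-membership constraint `a %in% pattern` becomes a membership test on
#' the concatenated items `{y1.a, ..., ym.a}`; a column-membership constraint
#' `y2 %in% cols` becomes membership over `{y2.s : s in alphabet}`. Aggregates
#' over the pattern stay aggregates over the symbol part of items (already how
#' evaluation works), so they are returned unchanged.
#'
#' @param constraint a `bic_constraint` targeting `pattern` or `cols`.
#' @param alphabet integer symbols in use.
#' @param columns column identifiers of the matrix.
#' @return a `bic_constraint` over items.
#' @export
translate_constraint <- function(constraint, alphabet, columns) {
  if (!length(alphabet)) stop("empty alphabet")
  if (!length(columns)) stop("empty column set")
  atoms <- lapply(constraint$atoms, function(a) {
    if (a$kind != "set") return(a)
    if (a$target == "pattern") {
      ann <- is_annotation_item(a$set)
      expanded <- c(
        unlist(lapply(a$set[!ann], function(s) make_item(columns, s))),
        a$set[ann]
      )
      a$set <- expanded
      a$target <- "items"
      a$text <- paste0("items ", a$rel, " {", paste(expanded, collapse = ","), "}")
    } else if (a$target == "cols") {
      expanded <- unlist(lapply(a$set, function(cl) make_item(cl, alphabet)))
      a$set <- expanded
      # one item per required column suffices: superset over columns becomes
      # "some symbol of each column present", i.e. contains per column
      a$target <- "items"
      if (a$rel == "superset") a$rel <- "contains_all_cols"
      a$text <- paste0("items ", a$rel, " {", paste(expanded, collapse = ","), "}")
    }
    a
  })
  structure(list(atoms = atoms, ops = constraint$ops, text = constraint$text),
            class = "bic_constraint")
}

#' Check that a constraint's operands exist in a database
#'
#' Soundness check run before mining: every referenced symbol, column, row or
#' annotation term must exist in the preprocessed database.
#'
#' @param constraint a `bic_constraint`.
#' @param db an `itemset_db` or `seq_db`.
#' @return invisibly `TRUE`; errors on an unbound operand.
#' @export
check_constraint_bound <- function(constraint, db) {
  if (inherits(db, "itemset_db")) {
    items <- unique(unlist(db$tx))
    parts <- split_items(items)
    known <- list(items = items, symbols = unique(parts$symbol[!is.na(parts$symbol)]),
                  cols = unique(parts$col[!is.na(parts$col)]), rows = names(db$tx))
  } else {
    cols <- unique(unlist(db$sequences))
    known <- list(items = cols, symbols = character(0), cols = cols,
                  rows = names(db$sequences))
  }
  for (a in constraint$atoms) {
    if (a$kind == "set") {
      universe <- switch(a$target,
        pattern = c(known$symbols, known$items),
        items = known$items, rows = known$rows, cols = known$cols)
      missing <- setdiff(a$set, universe)
      if (length(missing)) {
        stop("constraint operand(s) not present in database: ",
             paste(missing, collapse = ", "))
      }
    } else if (a$kind == "regex") {
      ids <- setdiff(unlist(a$tokens), "*")
      missing <- setdiff(ids, known$cols)
      if (length(missing)) {
        stop("regex column(s) not present in database: ", paste(missing, collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}
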