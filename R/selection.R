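#' Select atoms from a topology
#'
#' A small selection grammar shared by every analysis stage. Primitives:
#'
#' * `resid 91`, `resid 91:120`, `resid 91,95,100:110` — residue sequence
#'   numbers (author numbering, 1-based) and inclusive ranges
#' * `name CA`, `name CA,CB` — atom names
#' * `resname HOH,TIP3` — residue names
#' * `chain A` — chain identifiers
#' * `backbone` — atoms named N, CA, C, O
#' * `heavy` — non-hydrogen atoms
#' * `water` — atoms of residues whose name is in the topology's water set
#'
#' Primitives combine with `and` / `or` (`and` binds tighter) and may be
#' grouped with parentheses, e.g. `"resid 91 and heavy"`,
#' `"(resid 91 or resid 98) and name CA"`.
#'
#' @param topology A `gt_topology`.
#' @param spec Selection expression string.
#' @return Strictly increasing integer vector of atom indices (possibly
#'   empty).
#' @export
select_atoms <- function(topology, spec) {
  if (!is.character(spec) || length(spec) != 1 || is.na(spec) || !nzchar(trimws(spec)))
    rlang::abort("selection must be a non-empty string", class = "gpcrtraj_parse_error")
  at <- topology$atoms
  toks <- sel_tokenize(spec)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- sel_expr(st, at, topology)
  if (st$pos <= length(st$toks))
    rlang::abort(paste0("unexpected token in selection: '", st$toks[st$pos], "'"),
                 class = "gpcrtraj_parse_error")
  which(mask)
}

sel_tokenize <- function(spec) {
  spec <- gsub("\\(", " ( ", spec)
  spec <- gsub("\\)", " ) ", spec)
  toks <- strsplit(trimws(spec), "\\s+")[[1]]
  toks[nzchar(toks)]
}

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

sel_take <- function(st) {
  t <- sel_peek(st)
  if (is.na(t)) rlang::abort("selection ended unexpectedly", class = "gpcrtraj_parse_error")
  st$pos <- st$pos + 1L
  t
}

# expr := term ('or' term)*
sel_expr <- function(st, at, top) {
  m <- sel_term(st, at, top)
  while (identical(sel_peek(st), "or")) {
    sel_take(st)
    m <- m | sel_term(st, at, top)
  }
  m
}

# term := factor ('and' factor)*
sel_term <- function(st, at, top) {
  m <- sel_factor(st, at, top)
  while (identical(sel_peek(st), "and")) {
    sel_take(st)
    m <- m & sel_factor(st, at, top)
  }
  m
}

sel_factor <- function(st, at, top) {
  t <- sel_take(st)
  if (t == "(") {
    m <- sel_expr(st, at, top)
    if (!identical(sel_take(st), ")"))
      rlang::abort("missing ')' in selection", class = "gpcrtraj_parse_error")
    return(m)
  }
  switch(t,
    backbone = at$name %in% c("N", "CA", "C", "O"),
    heavy    = at$is_heavy,
    water    = at$resname %in% top$water_names,
    resid    = at$resid %in% sel_int_list(sel_take(st)),
    name     = at$name %in% sel_str_list(sel_take(st)),
    resname  = at$resname %in% sel_str_list(sel_take(st)),
    chain    = at$chain %in% sel_str_list(sel_take(st)),
    rlang::abort(paste0("unknown selection keyword: '", t, "'"),
                 class = "gpcrtraj_parse_error")
  )
}

sel_str_list <- function(tok) {
  out <- strsplit(tok, ",")[[1]]
  out <- out[nzchar(out)]
  if (length(out) == 0)
    rlang::abort("empty value list in selection", class = "gpcrtraj_parse_error")
  out
}

sel_int_list <- function(tok) {
  parts <- sel_str_list(tok)
  out <- integer(0)
  for (p in parts) {
    if (grepl("^-?[0-9]+[:-][0-9]+$", p)) {
      sep <- if (grepl(":", p)) ":" else "-"
      ab <- as.integer(strsplit(p, sep, fixed = TRUE)[[1]])
      out <- c(out, ab[1]:ab[2])
    } else if (grepl("^-?[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      rlang::abort(paste0("invalid residue specifier: '", p, "'"),
                   class = "gpcrtraj_parse_error")
    }
  }
  out
}
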