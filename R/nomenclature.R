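# Gene-symbol and variant-nomenclature standardization. Gene symbols are
# canonicalized against an HGNC table (a bundled subset covering the
# 49-gene panel plus common aliases; a full HGNC TSV can be supplied).
# Protein-level HGVS is stored in three-letter residue form only; one-letter
# input is expanded at the boundary. The wildcard residue Xaa is a
# query-side construct grouping all substitutions at a codon.

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              "*" = "Ter", X = "Xaa")

RES3 <- paste0("(?:", paste(AA_THREE, collapse = "|"), ")")
RES1 <- "[ACDEFGHIKLMNPQRSTVWYX*]"

one_to_three <- function(x) unname(AA_THREE[x])

# Grammar covered: substitution (incl. Ter and the synonymous '='),
# del / dup (single position or range), ins (range only, per HGVS),
# delins, and frameshift with optional Ter offset. Anything beyond
# (mosaicism, phasing, uncertain breakpoints, extensions) is rejected.
p_patterns <- function(res) {
  list(
    substitution = sprintf("^p\\.(%s)(\\d+)(%s|=)$", res, res),
    delins = sprintf("^p\\.(%s)(\\d+)(?:_(%s)(\\d+))?delins((?:%s)+)$",
                     res, res, res),
    deletion = sprintf("^p\\.(%s)(\\d+)(?:_(%s)(\\d+))?del$", res, res),
    duplication = sprintf("^p\\.(%s)(\\d+)(?:_(%s)(\\d+))?dup$", res, res),
    insertion = sprintf("^p\\.(%s)(\\d+)_(%s)(\\d+)ins((?:%s)+)$",
                        res, res, res),
    frameshift = sprintf("^p\\.(%s)(\\d+)(%s)?fs(?:(?:Ter|\\*)(\\d+))?$",
                         res, res)
  )
}

.P3 <- p_patterns(RES3)
.P1 <- p_patterns(RES1)

split_residues <- function(x, one_letter) {
  if (is.na(x) || x == "") return(NA_character_)
  if (one_letter) {
    res <- strsplit(x, "")[[1]]
    one_to_three(res)
  } else {
    regmatches(x, gregexpr(RES3, x, perl = TRUE))[[1]]
  }
}

match_p <- function(expr, one_letter) {
  pats <- if (one_letter) .P1 else .P3
  for (kind in names(pats)) {
    m <- regmatches(expr, regexec(pats[[kind]], expr, perl = TRUE))[[1]]
    if (length(m) > 0) return(list(kind = kind, groups = m[-1]))
  }
  NULL
}

first_bad_char <- function(expr) {
  # longest prefix still consistent with the grammar start: "p." + residue
  # + digits; report the 1-based position where it breaks down.
  if (!startsWith(expr, "p.")) return(1L)
  body <- substring(expr, 3)
  m <- regexpr(sprintf("^(?:%s|%s)\\d*", RES3, RES1), body, perl = TRUE)
  if (m == -1) return(3L)
  as.integer(3 + attr(m, "match.length"))
}

build_change <- function(kind, g, one_letter) {
  conv <- function(r) {
    if (is.na(r) || r == "") return(NA_character_)
    if (one_letter) one_to_three(r) else r
  }
  if (kind == "substitution") {
    alt <- g[3]
    if (alt == "=")
      return(protein_change("synonymous", conv(g[1]), as.integer(g[2])))
    return(protein_change("substitution", conv(g[1]), as.integer(g[2]),
                          alt = conv(alt)))
  }
  if (kind %in% c("deletion", "duplication")) {
    return(protein_change(kind, conv(g[1]), as.integer(g[2]),
                          end_ref = conv(g[3]),
                          end_pos = if (g[4] == "") NA_integer_ else as.integer(g[4])))
  }
  if (kind == "insertion") {
    return(protein_change("insertion", conv(g[1]), as.integer(g[2]),
                          end_ref = conv(g[3]), end_pos = as.integer(g[4]),
                          ins_seq = split_residues(g[5], one_letter)))
  }
  if (kind == "delins") {
    return(protein_change("delins", conv(g[1]), as.integer(g[2]),
                          end_ref = conv(g[3]),
                          end_pos = if (g[4] == "") NA_integer_ else as.integer(g[4]),
                          ins_seq = split_residues(g[5], one_letter)))
  }
  # frameshift
  protein_change("frameshift", conv(g[1]), as.integer(g[2]),
                 alt = conv(g[3]),
                 fs_ter = if (g[4] == "") NA_integer_ else as.integer(g[4]))
}

protein_change <- function(kind, ref, pos, end_ref = NA_character_,
                           end_pos = NA_integer_, alt = NA_character_,
                           ins_seq = NA_character_, fs_ter = NA_integer_) {
  structure(list(kind = kind, ref_residue = ref, position = pos,
                 end_ref_residue = end_ref, end_position = end_pos,
                 alt_residue = alt, ins_seq = ins_seq, fs_ter = fs_ter),
            class = "protein_change")
}

#' @export
print.protein_change <- function(x, ...) {
  cat(sprintf("<protein_change> %s (%s)\n", format_protein_hgvs(x), x$kind))
  invisible(x)
}

validate_change <- function(pc, expr, allow_wildcard) {
  if (identical(pc$ref_residue, "Xaa") || identical(pc$end_ref_residue, "Xaa"))
    stop_hgvs(expr, "Xaa is allowed only as the substituted residue of a pattern")
  has_x <- identical(pc$alt_residue, "Xaa") ||
    (!all(is.na(pc$ins_seq)) && any(pc$ins_seq == "Xaa"))
  if (has_x) {
    if (!allow_wildcard)
      stop_hgvs(expr, "wildcard residue Xaa not permitted in observed data")
    if (pc$kind != "substitution" || !identical(pc$alt_residue, "Xaa"))
      stop_hgvs(expr, "Xaa wildcard is only valid as the alternate residue of a substitution")
  }
  if (pc$kind == "substitution" && identical(pc$ref_residue, "Ter"))
    stop_hgvs(expr, "stop-loss expressions are not supported")
  if (pc$kind == "substitution" && identical(pc$alt_residue, pc$ref_residue))
    stop_hgvs(expr, "alternate equals reference; use 'p.Ref#=' for synonymous")
  if (!is.na(pc$end_position) && pc$end_position < pc$position)
    stop_hgvs(expr, "range end before range start")
  if (pc$kind == "frameshift" && identical(pc$ref_residue, "Ter"))
    stop_hgvs(expr, "frameshift cannot start at Ter")
  pc
}

stop_hgvs <- function(expr, msg, pos = NA_integer_) {
  stop(structure(
    class = c("gcdm_hgvs_error", "error", "condition"),
    list(message = if (is.na(pos)) sprintf("invalid HGVS '%s': %s", expr, msg)
         else sprintf("invalid HGVS '%s' at character %d: %s", expr, pos, msg),
         call = NULL, expr = expr, position = pos)))
}

#' Parse a protein-level HGVS expression
#'
#' Accepts canonical three-letter-residue expressions (`p.Leu858Arg`,
#' `p.Glu746_Ala750del`, `p.Leu747Profs*12`, `p.Gly12=`). One-letter input
#' is not accepted here; expand it first with [expand_protein_hgvs()].
#'
#' @param expr Expression beginning with `"p."`.
#' @param allow_wildcard Permit the query-side wildcard `Xaa` as the
#'   alternate residue of a substitution (e.g. `p.Gly12Xaa`). Observed
#'   (stored) expressions must be parsed with `allow_wildcard = FALSE`.
#' @return A `protein_change`: kind (substitution, synonymous, deletion,
#'   duplication, insertion, delins, frameshift), reference residue and
#'   position, optional range end, alternate residue, inserted sequence
#'   and frameshift Ter offset.
#' @examples
#' parse_protein_hgvs("p.Leu858Arg")
#' parse_protein_hgvs("p.Gly12Xaa", allow_wildcard = TRUE)
#' @export
parse_protein_hgvs <- function(expr, allow_wildcard = TRUE) {
  stopifnot(is.character(expr), length(expr) == 1)
  # memoized over distinct expressions: validation re-parses every stored
  # hgvs_p, so repeated loads of the same cohort hit the cache
  if (is.null(.gcdm_env$pcache))
    .gcdm_env$pcache <- new.env(parent = emptyenv(), hash = TRUE)
  key <- paste0(if (allow_wildcard) "w:" else "s:", expr)
  hit <- .gcdm_env$pcache[[key]]
  if (!is.null(hit)) return(hit)
  if (!startsWith(expr, "p."))
    stop_hgvs(expr, "protein HGVS must begin with 'p.'", 1L)
  m <- match_p(expr, one_letter = FALSE)
  if (is.null(m))
    stop_hgvs(expr, "does not match the supported grammar",
              first_bad_char(expr))
  pc <- validate_change(build_change(m$kind, m$groups, one_letter = FALSE),
                        expr, allow_wildcard)
  .gcdm_env$pcache[[key]] <- pc
  pc
}

# NULL when expr parses as stored (three-letter, no wildcard), else the
# error message; used by the database validator.
protein_hgvs_error <- function(expr) {
  tryCatch({
    parse_protein_hgvs(expr, allow_wildcard = FALSE)
    NULL
  }, error = function(e) conditionMessage(e))
}

#' Format a protein change back to HGVS text
#'
#' Inverse of [parse_protein_hgvs()]: formatting a parsed expression
#' reproduces it exactly (frameshift Ter offsets are normalized to the
#' `fsTer#` spelling).
#'
#' @param pc A `protein_change`.
#' @return Canonical three-letter HGVS string.
#' @export
format_protein_hgvs <- function(pc) {
  stopifnot(inherits(pc, "protein_change"))
  head <- sprintf("p.%s%d", pc$ref_residue, pc$position)
  range <- if (!is.na(pc$end_position))
    sprintf("_%s%d", pc$end_ref_residue, pc$end_position) else ""
  switch(pc$kind,
    substitution = paste0(head, pc$alt_residue),
    synonymous = paste0(head, "="),
    deletion = paste0(head, range, "del"),
    duplication = paste0(head, range, "dup"),
    insertion = paste0(head, range, "ins", paste(pc$ins_seq, collapse = "")),
    delins = paste0(head, range, "delins", paste(pc$ins_seq, collapse = "")),
    frameshift = paste0(head,
                        if (!is.na(pc$alt_residue)) pc$alt_residue else "",
                        "fs",
                        if (!is.na(pc$fs_ter)) sprintf("Ter%d", pc$fs_ter) else ""),
    stop(sprintf("unknown kind '%s'", pc$kind), call. = FALSE))
}

#' Expand protein HGVS to three-letter residue form
#'
#' One-letter residue codes are replaced by their three-letter equivalents
#' (`p.L858R` becomes `p.Leu858Arg`); `*` is normalized to `Ter`. Input
#' already in canonical three-letter form is returned unchanged, so the
#' operation is idempotent.
#'
#' @param expr Expression beginning with `"p."`, one- or three-letter.
#' @param allow_wildcard Permit `Xaa`/`X` wildcard (pattern context).
#' @return Canonical three-letter expression.
#' @examples
#' expand_protein_hgvs("p.L858R")
#' expand_protein_hgvs("p.Gly12Asp")
#' @export
expand_protein_hgvs <- function(expr, allow_wildcard = TRUE) {
  stopifnot(is.character(expr), length(expr) == 1)
  if (!startsWith(expr, "p."))
    stop_hgvs(expr, "protein HGVS must begin with 'p.'", 1L)
  m3 <- match_p(expr, one_letter = FALSE)
  if (!is.null(m3)) {
    pc <- validate_change(build_change(m3$kind, m3$groups, one_letter = FALSE),
                          expr, allow_wildcard)
    return(format_protein_hgvs(pc))
  }
  m1 <- match_p(expr, one_letter = TRUE)
  if (is.null(m1))
    stop_hgvs(expr, "does not match the supported grammar",
              first_bad_char(expr))
  pc <- validate_change(build_change(m1$kind, m1$groups, one_letter = TRUE),
                        expr, allow_wildcard)
  format_protein_hgvs(pc)
}

#' Match an observed protein change against a pattern
#'
#' A literal pattern matches only an identical change. A wildcard pattern
#' (alternate residue `Xaa`) matches any single-residue missense
#' substitution at the same reference residue and position: it does not
#' match nonsense (`Ter`), synonymous, or indel/frameshift events at that
#' codon, which are profiled separately.
#'
#' @param observed A `protein_change` or HGVS string (no wildcard).
#' @param pattern A `protein_change` or HGVS string, possibly with `Xaa`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' matches_pattern("p.Gly12Asp", "p.Gly12Xaa")
#' matches_pattern("p.Gly13Asp", "p.Gly12Xaa")
#' @export
matches_pattern <- function(observed, pattern) {
  if (is.character(observed))
    observed <- parse_protein_hgvs(observed, allow_wildcard = FALSE)
  if (is.character(pattern))
    pattern <- parse_protein_hgvs(pattern, allow_wildcard = TRUE)
  stopifnot(inherits(observed, "protein_change"),
            inherits(pattern, "protein_change"))
  if (identical(pattern$alt_residue, "Xaa")) {
    return(observed$kind == "substitution" &&
             observed$ref_residue == pattern$ref_residue &&
             observed$position == pattern$position &&
             !identical(observed$alt_residue, "Ter"))
  }
  identical(format_protein_hgvs(observed), format_protein_hgvs(pattern))
}

# ---- HGNC gene symbols ------------------------------------------------------

#' Load an HGNC symbol table
#'
#' @param path TSV with columns `symbol`, `canonical`, `hgnc_id`; rows map
#'   a symbol or alias (matched case-insensitively) to its canonical HGNC
#'   symbol and accession. Canonical symbols must map to themselves and an
#'   alias must never collide with a different canonical symbol.
#' @return An `hgnc_table` data frame.
#' @export
load_hgnc_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("symbol", "canonical", "hgnc_id")
  if (!all(need %in% names(df)))
    stop(sprintf("HGNC table must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  df$key <- toupper(df$symbol)
  canon <- toupper(df$canonical)
  self <- df$key %in% canon
  bad <- df$key[self & df$key != canon]
  if (length(bad) > 0)
    stop(sprintf("alias '%s' collides with a canonical symbol", bad[1]),
         call. = FALSE)
  if (anyDuplicated(df$key))
    stop(sprintf("duplicate symbol '%s' in HGNC table",
                 df$symbol[duplicated(df$key)][1]), call. = FALSE)
  structure(df, class = c("hgnc_table", "data.frame"))
}

#' Bundled HGNC subset (49-gene panel plus common aliases)
#'
#' @return An `hgnc_table`.
#' @export
default_hgnc_table <- function() {
  if (is.null(.gcdm_env$hgnc))
    .gcdm_env$hgnc <- load_hgnc_table(
      system.file("extdata", "hgnc_subset.tsv", package = "gcdm",
                  mustWork = TRUE))
  .gcdm_env$hgnc
}

#' Canonicalize a gene symbol
#'
#' Case-insensitive lookup of a symbol or alias; idempotent (canonical
#' symbols map to themselves).
#'
#' @param symbol Gene symbol or alias.
#' @param table An `hgnc_table`; defaults to the bundled subset.
#' @return List with `symbol` (canonical) and `hgnc_id`.
#' @examples
#' normalize_gene_symbol("egfr")
#' @export
normalize_gene_symbol <- function(symbol, table = default_hgnc_table()) {
  stopifnot(is.character(symbol), length(symbol) == 1)
  i <- match(toupper(symbol), table$key)
  if (is.na(i))
    stop(structure(
      class = c("gcdm_lookup_error", "error", "condition"),
      list(message = sprintf("unknown gene symbol '%s'", symbol),
           call = NULL, symbol = symbol)))
  list(symbol = table$canonical[i], hgnc_id = table$hgnc_id[i])
}

# Vectorized, non-throwing variant for ETL streams: NA where unknown.
normalize_gene_symbols <- function(symbols, table = default_hgnc_table()) {
  i <- match(toupper(symbols), table$key)
  table$canonical[i]
}

# ---- consequence / variant-type mapping -------------------------------------

#' Load a consequence-term mapping
#'
#' @param path JSON with maps `variant_feature` (source consequence term to
#'   protein-functional class), `sequence_alteration_from_feature`
#'   (consequence terms implying a DNA-structural class) and
#'   `sequence_alteration` (source structural terms, e.g. MAF
#'   `Variant_Type`, to the structural vocabulary).
#' @return A `feature_mapping` list.
#' @export
load_feature_mapping <- function(path) {
  fm <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(is.list(fm$variant_feature), is.list(fm$sequence_alteration))
  structure(fm, class = "feature_mapping")
}

#' Bundled MAF-dialect consequence mapping
#' @return A `feature_mapping`.
#' @export
default_feature_mapping <- function() {
  if (is.null(.gcdm_env$fmap))
    .gcdm_env$fmap <- load_feature_mapping(
      system.file("extdata", "feature_mapping.json", package = "gcdm",
                  mustWork = TRUE))
  .gcdm_env$fmap
}

#' Map a source consequence term to the model's variant classes
#'
#' Total over any input: unmapped terms route to `"other"` with a warning,
#' never an error.
#'
#' @param source_term Consequence term (e.g. MAF `Variant_Classification`
#'   or a Sequence Ontology term).
#' @param mapping A `feature_mapping`.
#' @return List with `variant_feature` and `sequence_alteration` (the
#'   latter `NA` unless the term implies a structural class, as
#'   `Frame_Shift_Del` implies a deletion).
#' @examples
#' map_consequence("Missense_Mutation")
#' map_consequence("Frame_Shift_Del")
#' @export
map_consequence <- function(source_term, mapping = default_feature_mapping()) {
  stopifnot(is.character(source_term), length(source_term) == 1)
  vf <- mapping$variant_feature[[source_term]]
  if (is.null(vf)) {
    warning(sprintf("unmapped consequence term '%s'; routed to 'other'",
                    source_term), call. = FALSE)
    return(list(variant_feature = "other", sequence_alteration = NA_character_))
  }
  sa <- mapping$sequence_alteration_from_feature[[source_term]]
  list(variant_feature = vf,
       sequence_alteration = if (is.null(sa)) NA_character_ else sa)
}

# Map a structural source term (MAF Variant_Type or panel-export class).
map_alteration <- function(source_term, mapping = default_feature_mapping()) {
  sa <- mapping$sequence_alteration[[toupper(source_term)]]
  if (is.null(sa)) NA_character_ else sa
}
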