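# Cohort analytics over a populated database: demographics, per-gene
# variant frequencies, two-level variant-type proportions, actionable-
# mutation profiling, waterfall matrices, HGVS queries, aggregate-only
# export with small-cell suppression, and two-site comparison with
# chi-squared tests. Everything here consumes counts and denominators;
# no per-patient row ever leaves through the aggregate path.

PROTEIN_ALTERING <- c("missense", "nonsense", "frameshift", "inframe",
                      "splice")

# Most-deleterious-first ordering used to pick the single class shown in a
# waterfall cell when a patient has several variants in one gene.
FEATURE_PRIORITY <- c("nonsense", "frameshift", "splice", "inframe",
                      "missense", "synonymous", "intron", "other")

AGE_BINS <- c("<=49", "50-59", "60-69", "70-79", ">=80", "unknown")

# Rounds half away from zero, the convention behind the printed one-decimal
# percentages (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

age_bin <- function(age) {
  ifelse(is.na(age), "unknown",
  ifelse(age <= 49, "<=49",
  ifelse(age <= 59, "50-59",
  ifelse(age <= 69, "60-69",
  ifelse(age <= 79, "70-79", ">=80")))))
}

# Joined per-variant view: one row per variant occurrence with its gene
# symbol, patient and patient's (first) condition.
variant_view <- function(db) {
  vo <- db$tables$variant_occurrence
  tg <- db$tables$target_gene
  pr <- db$tables$procedure_occurrence
  co <- db$tables$condition_occurrence
  co <- co[order(co$condition_id), ]
  first_cond <- co[!duplicated(co$person_id), ]
  person <- pr$person_id[match(vo$procedure_id, pr$procedure_id)]
  data.frame(
    variant_occurrence_id = vo$variant_occurrence_id,
    person_id = person,
    hgnc_symbol = tg$hgnc_symbol[match(vo$target_gene_id, tg$target_gene_id)],
    condition_name = first_cond$condition_name[
      match(person, first_cond$person_id)],
    hgvs_p = vo$hgvs_p,
    sequence_alteration = vo$sequence_alteration,
    variant_feature = vo$variant_feature,
    stringsAsFactors = FALSE)
}

#' Cohort demographics table
#'
#' Age (binned `<=49`, `50-59`, `60-69`, `70-79`, `>=80`, `unknown`),
#' gender, pathology (condition name) and cancer stage, each as count and
#' percent of the full cohort (unknown categories included in the
#' denominator), percent rounded half-up to one decimal.
#'
#' @param db A `gcdm_db` with person and condition rows loaded.
#' @return Data frame with columns `category_group`, `category`, `count`,
#'   `percent`.
#' @export
cohort_demographics <- function(db) {
  stopifnot(inherits(db, "gcdm_db"))
  pe <- db$tables$person
  n <- nrow(pe)
  if (n == 0)
    stop(structure(class = c("gcdm_empty_cohort", "error", "condition"),
                   list(message = "empty_cohort: no persons loaded",
                        call = NULL)))
  co <- db$tables$condition_occurrence
  co <- co[order(co$condition_id), ]
  first_cond <- co[!duplicated(co$person_id), ]
  cond_of <- first_cond[match(pe$person_id, first_cond$person_id), ]

  count_group <- function(group, values, levels) {
    values <- as.character(values)
    values[is.na(values)] <- "unknown"
    counts <- vapply(levels, function(l) sum(values == l), integer(1))
    data.frame(category_group = group, category = levels,
               count = unname(counts),
               percent = round_half_up(100 * unname(counts) / n, 1),
               stringsAsFactors = FALSE)
  }
  path_vals <- cond_of$condition_name
  path_vals[is.na(path_vals)] <- "unknown"
  path_levels <- names(sort(table(path_vals), decreasing = TRUE))
  rbind(
    count_group("age", age_bin(pe$age_years), AGE_BINS),
    count_group("gender", pe$gender, vocabulary("gender")),
    count_group("pathology", path_vals, path_levels),
    count_group("stage", cond_of$stage,
                c("I", "II", "III", "IV", "unknown")))
}

#' Per-gene variant frequency
#'
#' Fraction of cohort patients carrying at least one variant in each panel
#' gene; a patient counts at most once per gene and the denominator is the
#' full cohort, including patients with no variants.
#'
#' @param db A `gcdm_db`.
#' @param protein_altering_only Count only missense, nonsense, frameshift,
#'   inframe and splice variants.
#' @return Data frame `hgnc_symbol`, `n_patients_with_variant`,
#'   `n_patients_total`, `frequency`, ordered by frequency descending then
#'   symbol.
#' @export
gene_variant_frequency <- function(db, protein_altering_only = FALSE) {
  stopifnot(inherits(db, "gcdm_db"))
  n <- nrow(db$tables$person)
  if (n == 0)
    stop(structure(class = c("gcdm_empty_cohort", "error", "condition"),
                   list(message = "empty_cohort: no persons loaded",
                        call = NULL)))
  vv <- variant_view(db)
  if (protein_altering_only)
    vv <- vv[vv$variant_feature %in% PROTEIN_ALTERING, ]
  genes <- sort(unique(c(db$tables$target_gene$hgnc_symbol, vv$hgnc_symbol)))
  pg <- unique(vv[c("person_id", "hgnc_symbol")])
  counts <- vapply(genes, function(g) sum(pg$hgnc_symbol == g), integer(1))
  out <- data.frame(hgnc_symbol = genes,
                    n_patients_with_variant = unname(counts),
                    n_patients_total = n,
                    frequency = unname(counts) / n,
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$hgnc_symbol), , drop = FALSE]
}

#' Union of two sites' top-k genes
#'
#' @param a,b Gene-frequency tables from [gene_variant_frequency()].
#' @param k Number of top genes per table (ties broken alphabetically).
#' @return Character vector ordered by the maximum frequency across the
#'   two tables, descending, ties alphabetical.
#' @export
top_gene_union <- function(a, b, k = 10) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  top <- function(t) {
    t <- t[order(-t$frequency, t$hgnc_symbol), ]
    utils::head(t$hgnc_symbol, k)
  }
  genes <- union(top(a), top(b))
  fmax <- pmax(a$frequency[match(genes, a$hgnc_symbol)],
               b$frequency[match(genes, b$hgnc_symbol)], na.rm = TRUE)
  fmax[is.na(fmax)] <- 0
  genes[order(-fmax, genes)]
}

#' Variant-type proportions
#'
#' Proportions of variant rows (not patients) by DNA-structural class
#' (`sequence_alteration`) or protein-functional class (`variant_feature`).
#'
#' @param db A `gcdm_db`.
#' @param level `"sequence_alteration"` or `"variant_feature"`.
#' @return Data frame `type`, `count`, `proportion` over all vocabulary
#'   categories, in vocabulary order; proportions sum to 1.
#' @export
variant_type_proportions <- function(db,
                                     level = c("sequence_alteration",
                                               "variant_feature")) {
  stopifnot(inherits(db, "gcdm_db"))
  level <- match.arg(level)
  x <- db$tables$variant_occurrence[[level]]
  if (length(x) == 0)
    stop("no variants loaded", call. = FALSE)
  cats <- vocabulary(level)
  counts <- vapply(cats, function(c) sum(x == c), integer(1))
  data.frame(type = cats, count = unname(counts),
             proportion = unname(counts) / length(x),
             stringsAsFactors = FALSE)
}

# ---- actionable registry ----------------------------------------------------

#' Load an actionable-variant registry
#'
#' @param path JSON mapping gene symbols to protein-HGVS patterns, which
#'   may use the `Xaa` wildcard to group all substitutions at a codon.
#'   Every pattern must parse and every gene must canonicalize.
#' @param hgnc An `hgnc_table`.
#' @return An `actionable_registry`.
#' @export
load_registry <- function(path, hgnc = default_hgnc_table()) {
  r <- jsonlite::read_json(path, simplifyVector = FALSE)
  genes <- lapply(r$genes, function(pats) vapply(pats, function(p) {
    parse_protein_hgvs(p, allow_wildcard = TRUE)  # must parse
    p
  }, character(1), USE.NAMES = FALSE))
  names(genes) <- vapply(names(r$genes), function(g)
    normalize_gene_symbol(g, hgnc)$symbol, character(1))
  structure(list(name = r$name %||% "registry",
                 version = r$version %||% NA_character_, genes = genes),
            class = "actionable_registry")
}

#' Bundled NSCLC actionable-mutation registry
#' @return An `actionable_registry` covering EGFR, KRAS, PIK3CA, BRAF and
#'   NRAS hotspots.
#' @export
default_registry <- function() {
  load_registry(system.file("extdata", "actionable_registry.json",
                            package = "gcdm", mustWork = TRUE))
}

# For each registry pattern, the set of persons whose stored protein HGVS
# matches it. Parsing is cached over distinct expressions.
match_registry <- function(vv, registry) {
  obs <- vv[!is.na(vv$hgvs_p), , drop = FALSE]
  uniq <- unique(obs$hgvs_p)
  parsed <- lapply(uniq, function(x)
    tryCatch(parse_protein_hgvs(x, allow_wildcard = FALSE),
             error = function(e) NULL))
  names(parsed) <- uniq
  out <- list()
  for (gene in names(registry$genes)) {
    gv <- obs[obs$hgnc_symbol == gene, , drop = FALSE]
    for (pat in registry$genes[[gene]]) {
      ppat <- parse_protein_hgvs(pat, allow_wildcard = TRUE)
      hit <- vapply(gv$hgvs_p, function(h) {
        pc <- parsed[[h]]
        !is.null(pc) && matches_pattern(pc, ppat)
      }, logical(1), USE.NAMES = FALSE)
      out[[gene]][[pat]] <- unique(gv$person_id[hit])
    }
  }
  out
}

#' Actionable-mutation frequencies
#'
#' For every registry pattern (and, per gene, for "any pattern"), the
#' number and fraction of patients carrying a matching variant. A patient
#' counts once per pattern and once per gene across patterns. Registry
#' genes absent from the database's panel produce a warning, not an error.
#'
#' @param db A `gcdm_db`.
#' @param registry An `actionable_registry`.
#' @param stratify_by_condition Also report per condition (pathology),
#'   with per-condition denominators.
#' @return Data frame `condition` (`"(all)"` unless stratified), `gene`,
#'   `pattern` (`"(any)"` for the gene-level rows), `n_patients`,
#'   `n_total`, `frequency`.
#' @export
actionable_frequency <- function(db, registry = default_registry(),
                                 stratify_by_condition = FALSE) {
  stopifnot(inherits(db, "gcdm_db"), inherits(registry, "actionable_registry"))
  vv <- variant_view(db)
  panel_genes <- unique(db$tables$target_gene$hgnc_symbol)
  off <- setdiff(names(registry$genes), panel_genes)
  if (length(off) > 0)
    warning(sprintf("registry gene(s) not in panel: %s",
                    paste(off, collapse = ", ")), call. = FALSE)
  matches <- match_registry(vv, registry)
  pe <- db$tables$person
  co <- db$tables$condition_occurrence
  co <- co[order(co$condition_id), ]
  first_cond <- co[!duplicated(co$person_id), ]
  cond_of <- first_cond$condition_name[match(pe$person_id,
                                             first_cond$person_id)]

  strata <- list(`(all)` = pe$person_id)
  if (stratify_by_condition)
    for (cn in sort(unique(stats::na.omit(cond_of))))
      strata[[cn]] <- pe$person_id[!is.na(cond_of) & cond_of == cn]

  rows <- list()
  for (cn in names(strata)) {
    ids <- strata[[cn]]
    for (gene in names(registry$genes)) {
      gene_carriers <- integer(0)
      for (pat in registry$genes[[gene]]) {
        carriers <- intersect(matches[[gene]][[pat]], ids)
        gene_carriers <- union(gene_carriers, carriers)
        rows[[length(rows) + 1]] <- data.frame(
          condition = cn, gene = gene, pattern = pat,
          n_patients = length(carriers), n_total = length(ids),
          frequency = if (length(ids) > 0) length(carriers) / length(ids)
                      else NA_real_,
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        condition = cn, gene = gene, pattern = "(any)",
        n_patients = length(gene_carriers), n_total = length(ids),
        frequency = if (length(ids) > 0) length(gene_carriers) / length(ids)
                    else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(condition = character(), gene = character(),
                      pattern = character(), n_patients = integer(),
                      n_total = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Waterfall matrix
#'
#' Gene-by-patient mutation matrix: rows are genes ordered by variant
#' frequency (non-increasing), columns are patients ordered hierarchically
#' by mutation presence in gene order (the waterfall "staircase",
#' memo-sort; ties by person id), and each cell holds the single
#' highest-priority variant class among that patient's variants in that
#' gene (nonsense > frameshift > splice > inframe > missense > synonymous
#' > intron > other) or `"none"`.
#'
#' @param db A `gcdm_db`.
#' @param genes Gene symbols to show; default: top `top_n` by frequency.
#' @param top_n Number of genes when `genes` is `NULL`.
#' @param protein_altering_only Restrict to protein-altering variants, as
#'   in the published variant-profile figures.
#' @return A `gcdm_waterfall`: list with `genes`, `patients`, `matrix`
#'   (character, genes x patients), `frequencies`, and `clinical` (age,
#'   gender, condition per patient).
#' @export
waterfall_matrix <- function(db, genes = NULL, top_n = 10,
                             protein_altering_only = TRUE) {
  stopifnot(inherits(db, "gcdm_db"))
  freq <- gene_variant_frequency(db, protein_altering_only)
  if (is.null(genes)) {
    genes <- utils::head(freq$hgnc_symbol, top_n)
  } else {
    miss <- setdiff(genes, freq$hgnc_symbol)
    f <- c(stats::setNames(freq$frequency, freq$hgnc_symbol),
           stats::setNames(rep(0, length(miss)), miss))[genes]
    genes <- genes[order(-f, genes)]
  }
  gfreq <- freq$frequency[match(genes, freq$hgnc_symbol)]
  gfreq[is.na(gfreq)] <- 0

  vv <- variant_view(db)
  if (protein_altering_only)
    vv <- vv[vv$variant_feature %in% PROTEIN_ALTERING, ]
  vv <- vv[vv$hgnc_symbol %in% genes, , drop = FALSE]
  pe <- db$tables$person
  patients <- pe$person_id

  mat <- matrix("none", nrow = length(genes), ncol = length(patients),
                dimnames = list(genes, as.character(patients)))
  if (nrow(vv) > 0) {
    pri <- match(vv$variant_feature, FEATURE_PRIORITY)
    ord <- order(pri)  # best first; first write wins below
    for (i in ord) {
      g <- vv$hgnc_symbol[i]; p <- as.character(vv$person_id[i])
      if (mat[g, p] == "none") mat[g, p] <- vv$variant_feature[i]
    }
  }
  # memo-sort: treat each patient's presence/absence down the gene order
  # as a binary string, most significant gene first
  presence <- mat != "none"
  key <- apply(presence, 2, function(col)
    paste(as.integer(col), collapse = ""))
  ord <- order(-xtfrm(key), patients)
  mat <- mat[, ord, drop = FALSE]
  patients <- patients[ord]

  co <- db$tables$condition_occurrence
  co <- co[order(co$condition_id), ]
  first_cond <- co[!duplicated(co$person_id), ]
  clinical <- data.frame(
    person_id = patients,
    age_years = pe$age_years[match(patients, pe$person_id)],
    gender = pe$gender[match(patients, pe$person_id)],
    condition = first_cond$condition_name[match(patients,
                                                first_cond$person_id)],
    stringsAsFactors = FALSE)
  structure(list(genes = genes, patients = patients, matrix = mat,
                 frequencies = stats::setNames(gfreq, genes),
                 clinical = clinical),
            class = "gcdm_waterfall")
}

#' @export
print.gcdm_waterfall <- function(x, ...) {
  cat(sprintf("<gcdm_waterfall> %d genes x %d patients\n",
              length(x$genes), length(x$patients)))
  for (i in seq_along(x$genes))
    cat(sprintf("  %-10s %5.1f%%\n", x$genes[i], 100 * x$frequencies[i]))
  invisible(x)
}

#' Query patients carrying a variant
#'
#' Proportion of cohort patients with any variant in a gene, or with a
#' variant matching a protein-HGVS pattern (wildcards allowed).
#'
#' @param db A `gcdm_db`.
#' @param gene Gene symbol or alias.
#' @param hgvs_pattern Optional pattern, e.g. `"p.Leu858Arg"` or
#'   `"p.Gly12Xaa"`; `NULL` counts any variant in the gene.
#' @return List with `n_patients`, `n_total`, `frequency`.
#' @examples
#' db <- two_site_fixture(seed = 1)$site_a
#' query_variant(db, "EGFR", "p.Leu858Arg")
#' @export
query_variant <- function(db, gene, hgvs_pattern = NULL) {
  stopifnot(inherits(db, "gcdm_db"))
  gene <- normalize_gene_symbol(gene)$symbol
  n <- nrow(db$tables$person)
  vv <- variant_view(db)
  vv <- vv[vv$hgnc_symbol == gene, , drop = FALSE]
  if (is.null(hgvs_pattern)) {
    carriers <- unique(vv$person_id)
  } else {
    pat <- parse_protein_hgvs(expand_protein_hgvs(hgvs_pattern),
                              allow_wildcard = TRUE)
    obs <- vv[!is.na(vv$hgvs_p), , drop = FALSE]
    hit <- vapply(obs$hgvs_p, function(h)
      tryCatch(matches_pattern(h, pat), error = function(e) FALSE),
      logical(1), USE.NAMES = FALSE)
    carriers <- unique(obs$person_id[hit])
  }
  list(n_patients = length(carriers), n_total = n,
       frequency = if (n > 0) length(carriers) / n else NA_real_)
}

# ---- aggregate export and comparison ----------------------------------------

suppress_counts <- function(x, k) {
  if (k <= 0) return(x)
  rapply(x, function(v) {
    if (is.numeric(v) && length(v) == 1 && !is.na(v) && v > 0 && v < k)
      sprintf("<%d", k)
    else v
  }, how = "replace")
}

#' Export a privacy-preserving aggregate report
#'
#' A summary of the cohort containing only counts and denominators —
#' demographics, per-gene patient counts, variant-type counts at both
#' levels, actionable-mutation counts overall and per condition, and the
#' panel gene list — suitable for crossing site boundaries in a
#' distributed research network. No person, specimen or per-patient row
#' appears in the output. With `suppression_k > 0`, any count strictly
#' between 0 and k is masked as `"<k"` to reduce re-identification risk.
#'
#' @param db A `gcdm_db`.
#' @param site_label Label identifying the exporting site.
#' @param suppression_k Small-cell suppression threshold; 0 disables.
#' @param registry An `actionable_registry`.
#' @return A `gcdm_aggregate` list with deterministic (sorted) keys.
#' @export
export_aggregate <- function(db, site_label, suppression_k = 0,
                             registry = default_registry()) {
  stopifnot(inherits(db, "gcdm_db"))
  demo <- cohort_demographics(db)
  demo_counts <- lapply(split(demo, demo$category_group), function(d)
    as.list(stats::setNames(d$count, d$category))[order(d$category)])
  gf <- gene_variant_frequency(db)
  gf <- gf[order(gf$hgnc_symbol), ]
  vt_sa <- variant_type_proportions(db, "sequence_alteration")
  vt_vf <- variant_type_proportions(db, "variant_feature")
  act <- suppressWarnings(
    actionable_frequency(db, registry, stratify_by_condition = TRUE))
  act$item <- paste(act$gene, act$pattern)
  act_counts <- lapply(split(act, act$condition), function(d) {
    d <- d[order(d$item), ]
    as.list(stats::setNames(d$n_patients, d$item))
  })
  act_denoms <- lapply(split(act, act$condition), function(d)
    unique(d$n_total)[1])

  rep <- list(
    schema_version = gcdm_schema()$schema_version,
    site = site_label,
    n_patients = nrow(db$tables$person),
    n_variants = nrow(db$tables$variant_occurrence),
    demographics = demo_counts[order(names(demo_counts))],
    genes = as.list(stats::setNames(gf$n_patients_with_variant,
                                    gf$hgnc_symbol)),
    sequence_alteration = as.list(stats::setNames(vt_sa$count, vt_sa$type)),
    variant_feature = as.list(stats::setNames(vt_vf$count, vt_vf$type)),
    actionable = act_counts[order(names(act_counts))],
    actionable_denominators = act_denoms[order(names(act_denoms))],
    registry = registry$name,
    panel = sort(unique(db$tables$target_gene$hgnc_symbol)),
    suppression_k = suppression_k)
  rep <- suppress_counts(rep, suppression_k)
  structure(rep, class = "gcdm_aggregate")
}

#' @export
print.gcdm_aggregate <- function(x, ...) {
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE), "\n")
  invisible(x)
}

#' Write an aggregate report as JSON
#' @param report A `gcdm_aggregate`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_aggregate <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read an aggregate report written by [write_aggregate()]
#' @param path JSON file.
#' @return A `gcdm_aggregate`.
#' @export
read_aggregate <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "gcdm_aggregate")
}

#' Pearson chi-squared test on a 2x2 proportion table
#'
#' Compares a/n1 against b/n2 via the Pearson statistic without continuity
#' correction on the table `[[a, n1-a], [b, n2-b]]`, with the p-value from
#' the upper tail of the chi-squared distribution with one degree of
#' freedom.
#'
#' @param a,n1 Successes and total in group 1.
#' @param b,n2 Successes and total in group 2.
#' @return List with `statistic`, `p_value`, `df`.
#' @examples
#' chi_squared_2x2(30, 100, 10, 100)
#' @export
chi_squared_2x2 <- function(a, n1, b, n2) {
  stopifnot(n1 > 0, n2 > 0, a >= 0, b >= 0, a <= n1, b <= n2)
  if (a + b == 0 || (n1 - a) + (n2 - b) == 0)
    stop(structure(class = c("gcdm_degenerate_table", "error", "condition"),
                   list(message = "degenerate 2x2 table: a zero margin",
                        call = NULL)))
  tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2, byrow = TRUE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

agg_is_suppressed <- function(v) is.character(v)

#' Compare two aggregate reports
#'
#' Frequency ratios and chi-squared tests for every shared item: per-gene
#' patient counts (over cohort sizes), overall actionable-mutation counts,
#' and variant-type counts at both levels (over variant totals). Reports
#' must share schema version and panel; comparing suppressed cells is an
#' error. Ratios are reported to two decimals; items degenerate for the
#' chi-squared test (zero in both groups) carry a note instead.
#'
#' @param x,y `gcdm_aggregate` reports.
#' @param alpha Significance threshold for the flag column.
#' @param bonferroni Divide `alpha` by the number of items (off by
#'   default; no multiplicity correction is applied otherwise).
#' @return Data frame `item`, `freq_x`, `freq_y`, `ratio`, `chi2`, `p`,
#'   `significant`, `note`.
#' @export
compare_aggregates <- function(x, y, alpha = 0.05, bonferroni = FALSE) {
  stopifnot(inherits(x, "gcdm_aggregate"), inherits(y, "gcdm_aggregate"))
  if (!identical(x$schema_version, y$schema_version))
    stop("aggregate reports have different schema versions", call. = FALSE)
  if (!identical(sort(unlist(x$panel)), sort(unlist(y$panel))))
    stop("aggregate reports cover different panels", call. = FALSE)

  items <- list()
  push <- function(item, a, n1, b, n2) {
    items[[length(items) + 1]] <<- list(item = item, a = a, n1 = n1,
                                        b = b, n2 = n2)
  }
  for (g in sort(unique(c(names(x$genes), names(y$genes)))))
    push(paste0("gene:", g), x$genes[[g]] %||% 0L, x$n_patients,
         y$genes[[g]] %||% 0L, y$n_patients)
  ax <- x$actionable[["(all)"]]; ay <- y$actionable[["(all)"]]
  for (it in sort(unique(c(names(ax), names(ay)))))
    push(paste0("actionable:", it), ax[[it]] %||% 0L,
         x$actionable_denominators[["(all)"]], ay[[it]] %||% 0L,
         y$actionable_denominators[["(all)"]])
  for (lvl in c("sequence_alteration", "variant_feature"))
    for (t in sort(unique(c(names(x[[lvl]]), names(y[[lvl]])))))
      push(paste0(lvl, ":", t), x[[lvl]][[t]] %||% 0L, x$n_variants,
           y[[lvl]][[t]] %||% 0L, y$n_variants)

  thr <- if (bonferroni) alpha / length(items) else alpha
  rows <- lapply(items, function(it) {
    if (agg_is_suppressed(it$a) || agg_is_suppressed(it$b))
      stop(sprintf("item '%s' has a suppressed cell; cannot compare",
                   it$item), call. = FALSE)
    if (it$n1 == 0 || it$n2 == 0)
      return(data.frame(item = it$item, freq_x = NA_real_, freq_y = NA_real_,
                        ratio = NA_real_, chi2 = NA_real_, p = NA_real_,
                        significant = NA, note = "zero_denominator",
                        stringsAsFactors = FALSE))
    fx <- it$a / it$n1; fy <- it$b / it$n2
    ratio <- if (fy > 0) round_half_up(fx / fy, 2) else NA_real_
    res <- tryCatch(chi_squared_2x2(it$a, it$n1, it$b, it$n2),
                    error = function(e) NULL)
    data.frame(item = it$item, freq_x = fx, freq_y = fy, ratio = ratio,
               chi2 = if (is.null(res)) NA_real_ else res$statistic,
               p = if (is.null(res)) NA_real_ else res$p_value,
               significant = if (is.null(res)) NA else res$p_value < thr,
               note = if (is.null(res)) "degenerate_table"
                      else if (fy == 0) "zero_reference_frequency" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
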