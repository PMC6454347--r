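# Self-contained synthetic cohorts: exact demographic fixtures mirroring
# the two study sites (a 114-patient targeted-panel cohort and a
# 1060-patient WES cohort restricted to the same 49-gene panel), and a
# stochastic variant generator with configurable per-gene and per-pattern
# probabilities. Generated databases always pass validate_database.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Exact per-category counts behind the demographic fixtures. Age bins use
# representative in-bin ages so that binning reproduces the counts.
TABLE1_COUNTS <- list(
  ausom_like = list(
    n = 114L,
    age = c("<=49" = 7L, "50-59" = 26L, "60-69" = 41L, "70-79" = 35L,
            ">=80" = 5L, unknown = 0L),
    gender = c(male = 64L, female = 50L, unknown = 0L),
    pathology = c("lung adenocarcinoma" = 92L,
                  "lung squamous cell carcinoma" = 22L),
    stage = c(I = 78L, II = 16L, III = 18L, IV = 0L, unknown = 2L)),
  tcga_like = list(
    n = 1060L,
    age = c("<=49" = 44L, "50-59" = 163L, "60-69" = 310L, "70-79" = 317L,
            ">=80" = 56L, unknown = 170L),
    gender = c(male = 628L, female = 429L, unknown = 3L),
    pathology = c("lung adenocarcinoma" = 603L,
                  "lung squamous cell carcinoma" = 457L),
    stage = c(I = 526L, II = 286L, III = 184L, IV = 36L, unknown = 28L))
)

AGE_REPRESENTATIVE <- c("<=49" = 45L, "50-59" = 55L, "60-69" = 65L,
                        "70-79" = 75L, ">=80" = 85L, unknown = NA_integer_)

expand_counts <- function(counts) rep(names(counts), times = counts)

#' Exact demographic fixture for one study site
#'
#' Builds the clinical tables (person + condition) of a cohort whose
#' demographic margins match the reference cohorts exactly: the
#' targeted-panel site (`ausom_like`, N=114) or the WES site restricted to
#' the same panel (`tcga_like`, N=1060). Attributes are assigned blockwise
#' per category with deterministic person ids; only the margins, not the
#' joint distribution, are modeled.
#'
#' @param site `"ausom_like"` or `"tcga_like"`.
#' @param id_offset Offset added to every person/condition id (used to
#'   keep keys disjoint when pooling sites).
#' @return A `gcdm_db` with person and condition_occurrence populated.
#' @export
table1_fixture <- function(site = c("ausom_like", "tcga_like"),
                           id_offset = 0L) {
  site <- match.arg(site)
  tc <- TABLE1_COUNTS[[site]]
  n <- tc$n
  db <- init_database()
  ids <- id_offset + seq_len(n)
  insert_records(db, "person", data.frame(
    person_id = ids,
    gender = expand_counts(tc$gender),
    age_years = unname(AGE_REPRESENTATIVE[expand_counts(tc$age)]),
    race = NA_character_, stringsAsFactors = FALSE))
  insert_records(db, "condition_occurrence", data.frame(
    condition_id = ids, person_id = ids,
    condition_name = expand_counts(tc$pathology),
    condition_type = "primary condition",
    stage = expand_counts(tc$stage), stringsAsFactors = FALSE))
  db
}

#' Specification of a synthetic cohort
#'
#' @param n_patients Cohort size.
#' @param panel A `panel_definition`.
#' @param gene_probs Named vector: per-patient probability of carrying at
#'   least one variant in each gene (genes not named get probability 0).
#' @param pattern_probs Nested list, gene to named probability vector over
#'   protein-HGVS patterns (wildcards allowed), e.g.
#'   `list(KRAS = c("p.Gly12Xaa" = 0.2))`: per-patient probability of
#'   carrying a variant matching the pattern, drawn independently of
#'   `gene_probs`.
#' @param feature_weights Distribution over the protein-functional classes
#'   used for background variants; must sum to 1.
#' @param alteration_weights Distribution over the DNA-structural classes;
#'   must sum to 1. Zero weight on CNV/translocation yields a
#'   SNP/INDEL-only cohort.
#' @param demographics `"ausom_like"` or `"tcga_like"`: margins are scaled
#'   to probabilities and sampled at `n_patients`.
#' @param lambda_extra Mean of the Poisson number of extra variants beyond
#'   the first in a mutated patient-gene (exercises per-patient
#'   deduplication and cell-priority rules).
#' @param seed Integer seed; generation is fully reproducible.
#' @param id_offset Offset for all surrogate keys.
#' @param site_label Care-site name.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, panel = default_panel(),
                        gene_probs = c(), pattern_probs = list(),
                        feature_weights = c(missense = 0.6, nonsense = 0.1,
                                            frameshift = 0.1, inframe = 0.05,
                                            splice = 0.05, synonymous = 0.05,
                                            intron = 0.04, other = 0.01),
                        alteration_weights = c(SNP = 0.8, insertion = 0.1,
                                               deletion = 0.1, MNP = 0,
                                               CNV = 0, translocation = 0),
                        demographics = "ausom_like", lambda_extra = 0.3,
                        seed = 1L, id_offset = 0L, site_label = "site") {
  stopifnot(n_patients >= 1, inherits(panel, "panel_definition"),
            lambda_extra >= 0)
  if (length(gene_probs) > 0) {
    stopifnot(all(gene_probs >= 0 & gene_probs <= 1))
    bad <- setdiff(names(gene_probs), panel$genes)
    if (length(bad) > 0)
      stop(sprintf("gene_probs gene(s) not in panel: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (g in names(pattern_probs)) {
    if (!g %in% panel$genes)
      stop(sprintf("pattern_probs gene '%s' not in panel", g), call. = FALSE)
    stopifnot(all(pattern_probs[[g]] >= 0 & pattern_probs[[g]] <= 1))
    for (p in names(pattern_probs[[g]]))
      parse_protein_hgvs(p, allow_wildcard = TRUE)
  }
  check_w <- function(w, voc) {
    stopifnot(all(names(w) %in% vocabulary(voc)), all(w >= 0),
              abs(sum(w) - 1) < 1e-9)
  }
  check_w(feature_weights, "variant_feature")
  check_w(alteration_weights, "sequence_alteration")
  stopifnot(demographics %in% names(TABLE1_COUNTS))
  structure(list(n_patients = as.integer(n_patients), panel = panel,
                 gene_probs = gene_probs, pattern_probs = pattern_probs,
                 feature_weights = feature_weights,
                 alteration_weights = alteration_weights,
                 demographics = demographics,
                 lambda_extra = lambda_extra, seed = as.integer(seed),
                 id_offset = as.integer(id_offset),
                 site_label = site_label),
            class = "cohort_spec")
}

AA20 <- setdiff(unname(AA_THREE), c("Ter", "Xaa"))

# Random protein HGVS strings consistent with each functional class;
# splice/intron/CNV-like classes carry DNA-level HGVS only.
random_hgvs <- function(features) {
  n <- length(features)
  ref <- sample(AA20, n, replace = TRUE)
  off <- sample(19L, n, replace = TRUE)
  alt <- AA20[(match(ref, AA20) + off - 1L) %% 20L + 1L]
  pos <- sample(800L, n, replace = TRUE)
  fs_ter <- sample(60L, n, replace = TRUE)
  hp <- rep(NA_character_, n)
  hc <- sprintf("c.%d%s>%s", sample(2400L, n, replace = TRUE),
                sample(c("A", "C", "G", "T"), n, replace = TRUE),
                sample(c("A", "C", "G", "T"), n, replace = TRUE))
  m <- features == "missense"
  hp[m] <- sprintf("p.%s%d%s", ref[m], pos[m], alt[m])
  m <- features == "nonsense"
  hp[m] <- sprintf("p.%s%dTer", ref[m], pos[m])
  m <- features == "frameshift"
  hp[m] <- sprintf("p.%s%d%sfsTer%d", ref[m], pos[m], alt[m], fs_ter[m])
  m <- features == "inframe"
  hp[m] <- sprintf("p.%s%d_%s%ddel", ref[m], pos[m], alt[m], pos[m] + 2L)
  m <- features == "synonymous"
  hp[m] <- sprintf("p.%s%d=", ref[m], pos[m])
  m <- features %in% c("splice", "intron")
  hc[m] <- sprintf("c.%d+1G>A", pos[m])
  list(hgvs_p = hp, hgvs_c = hc)
}

# Instantiate a registry-style pattern as a concrete stored variant;
# wildcards draw uniformly over the 19 non-reference residues.
instantiate_pattern <- function(pattern, n) {
  pc <- parse_protein_hgvs(pattern, allow_wildcard = TRUE)
  if (identical(pc$alt_residue, "Xaa")) {
    alts <- sample(setdiff(AA20, pc$ref_residue), n, replace = TRUE)
    hgvs <- sprintf("p.%s%d%s", pc$ref_residue, pc$position, alts)
    feature <- rep("missense", n)
  } else {
    hgvs <- rep(format_protein_hgvs(pc), n)
    feature <- rep(switch(pc$kind,
                          substitution = if (identical(pc$alt_residue, "Ter"))
                            "nonsense" else "missense",
                          synonymous = "synonymous",
                          frameshift = "frameshift",
                          deletion = , duplication = , insertion = ,
                          delins = "inframe", "other"), n)
  }
  list(hgvs_p = hgvs, feature = feature)
}

#' Generate a synthetic cohort database
#'
#' Per patient, each gene with an entry in `gene_probs` mutates
#' independently; a mutated patient-gene receives `1 + Poisson(lambda)`
#' variants whose functional and structural classes are drawn from the
#' weight tables, with protein HGVS generated consistently with the class.
#' Independently, each `pattern_probs` entry makes the patient a carrier
#' of a variant matching that pattern (wildcards instantiated uniformly
#' over the 19 non-reference residues). Demographics are sampled from the
#' chosen site's margins. The result always passes [validate_database()].
#'
#' @param spec A `cohort_spec`.
#' @return A `gcdm_db`.
#' @examples
#' spec <- cohort_spec(20, gene_probs = c(EGFR = 1.0), seed = 7)
#' db <- generate_cohort(spec)
#' query_variant(db, "EGFR")
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    off <- spec$id_offset
    db <- init_database()
    ids <- off + seq_len(n)
    tc <- TABLE1_COUNTS[[spec$demographics]]
    draw <- function(counts) sample(names(counts), n, replace = TRUE,
                                    prob = counts / sum(counts))
    insert_records(db, "person", data.frame(
      person_id = ids, gender = draw(tc$gender),
      age_years = unname(AGE_REPRESENTATIVE[draw(tc$age)]),
      race = NA_character_, stringsAsFactors = FALSE))
    insert_records(db, "condition_occurrence", data.frame(
      condition_id = ids, person_id = ids,
      condition_name = draw(tc$pathology),
      condition_type = "primary condition", stage = draw(tc$stage),
      stringsAsFactors = FALSE))
    # panel registration with offset-disjoint surrogate keys
    care_site_id <- off + 1L
    gtid <- off + 1L
    insert_records(db, "care_site", data.frame(
      care_site_id = care_site_id, site_name = spec$site_label))
    insert_records(db, "genomic_test", data.frame(
      genomic_test_id = gtid, care_site_id = care_site_id,
      test_name = spec$panel$test_name,
      test_version = spec$panel$test_version,
      sequencing_device = spec$panel$sequencing_device,
      analytical_tools = spec$panel$analytical_tools,
      reference_databases = spec$panel$reference_databases,
      reference_genome_build = spec$panel$reference_genome_build,
      stringsAsFactors = FALSE))
    tg_ids <- off + seq_along(spec$panel$genes)
    insert_records(db, "target_gene", data.frame(
      target_gene_id = tg_ids, genomic_test_id = gtid,
      hgnc_symbol = spec$panel$genes, hgnc_id = spec$panel$hgnc_ids,
      stringsAsFactors = FALSE))
    gene_id_of <- stats::setNames(tg_ids, spec$panel$genes)
    insert_records(db, "procedure_occurrence", data.frame(
      procedure_id = ids, person_id = ids,
      acquisition_method = "biopsy",
      genomic_test_name = spec$panel$test_name, stringsAsFactors = FALSE))
    insert_records(db, "specimen", data.frame(
      specimen_id = ids, person_id = ids, specimen_role = "target",
      specimen_type = "paraffin-embedded slide",
      collection_date = NA_character_, anatomic_site = "lung",
      stringsAsFactors = FALSE))

    # background gene mutations
    pat_i <- integer(0); gene_i <- character(0)
    feat <- character(0); hp <- character(0); hc <- character(0)
    alt <- character(0)
    if (length(spec$gene_probs) > 0) {
      gp <- spec$gene_probs
      hitmat <- matrix(stats::runif(n * length(gp)) <
                         rep(gp, each = n), nrow = n)
      hits <- which(hitmat, arr.ind = TRUE)
      if (nrow(hits) > 0) {
        mult <- 1L + stats::rpois(nrow(hits), spec$lambda_extra)
        pat_i <- rep(hits[, 1], mult)
        gene_i <- rep(names(gp)[hits[, 2]], mult)
        tot <- length(pat_i)
        feat <- sample(names(spec$feature_weights), tot, replace = TRUE,
                       prob = spec$feature_weights)
        alt <- sample(names(spec$alteration_weights), tot, replace = TRUE,
                      prob = spec$alteration_weights)
        hv <- random_hgvs(feat)
        hp <- hv$hgvs_p; hc <- hv$hgvs_c
        # structural classes without protein-level consequence
        hp[alt %in% c("CNV", "translocation")] <- NA_character_
      }
    }
    # pattern carriers
    for (g in names(spec$pattern_probs)) {
      pp <- spec$pattern_probs[[g]]
      for (p in names(pp)) {
        carriers <- which(stats::runif(n) < pp[[p]])
        if (length(carriers) == 0) next
        inst <- instantiate_pattern(p, length(carriers))
        pat_i <- c(pat_i, carriers)
        gene_i <- c(gene_i, rep(g, length(carriers)))
        feat <- c(feat, inst$feature)
        alt <- c(alt, rep("SNP", length(carriers)))
        hp <- c(hp, inst$hgvs_p)
        hc <- c(hc, rep(NA_character_, length(carriers)))
      }
    }
    if (length(pat_i) > 0) {
      vo <- data.frame(
        variant_occurrence_id = off + seq_along(pat_i),
        procedure_id = off + pat_i,
        specimen_id_target = off + pat_i,
        specimen_id_reference = NA_integer_,
        target_gene_id = unname(gene_id_of[gene_i]),
        reference_sequence = NA_character_, rs_id = NA_character_,
        hgvs_c = hc, hgvs_p = hp,
        read_depth = stats::rpois(length(pat_i), 500),
        exon_number = sample(20L, length(pat_i), replace = TRUE),
        sequence_alteration = alt, variant_feature = feat,
        genomic_start = NA_integer_, genomic_end = NA_integer_,
        stringsAsFactors = FALSE)
      insert_records(db, "variant_occurrence", vo)
    }
    db
  })
}

# Study-condition defaults for the two emulated sites. Site A reflects a
# clinical targeted-panel cohort: very high per-gene variant burden,
# intron+synonymous-dominated functional classes (combined weight 0.83),
# the full structural-type mix including CNV and translocation, and the
# published actionable-pattern frequencies. Site B reflects the
# WES-derived research cohort restricted to the same panel: lower burden,
# missense-dominated (weight 0.73), SNP/INDEL only.
site_a_defaults <- function() {
  genes <- default_panel()$genes
  gp <- stats::setNames(
    0.30 + 0.40 * (seq_along(genes) - 1) %% 20 / 19, genes)
  # EGFR background is set so that the marginal probability of any EGFR
  # variant, background or actionable-pattern carrier, is 0.895:
  # 1 - (1 - 0.870)(1 - 0.175)(1 - 0.018) = 0.895
  gp[c("TP53", "EGFR", "KRAS", "PIK3CA", "BRAF", "NRAS", "RET", "ALK",
       "ROS1", "MET")] <-
    c(0.90, 0.870, 0.82, 0.80, 0.78, 0.76, 0.85, 0.79, 0.77, 0.81)
  list(gene_probs = gp,
       pattern_probs = list(
         EGFR = c("p.Leu858Arg" = 0.175, "p.Thr790Met" = 0.018),
         KRAS = c("p.Gly12Xaa" = 0.080, "p.Gly13Xaa" = 0.017)),
       feature_weights = c(missense = 0.09, nonsense = 0.02,
                           frameshift = 0.02, inframe = 0.01,
                           splice = 0.01, synonymous = 0.38,
                           intron = 0.45, other = 0.02),
       alteration_weights = c(SNP = 0.84, insertion = 0.05,
                              deletion = 0.05, MNP = 0.03, CNV = 0.02,
                              translocation = 0.01))
}

site_b_defaults <- function() {
  genes <- default_panel()$genes
  gp <- stats::setNames(0.02 + 0.10 * (seq_along(genes) - 1) %% 10 / 9,
                        genes)
  # EGFR marginal 0.115 after the p.Leu858Arg carriers:
  # 1 - (1 - 0.091)(1 - 0.0264) = 0.115
  gp[c("TP53", "EGFR", "KRAS", "STK11", "KEAP1", "NF1")] <-
    c(0.30, 0.091, 0.02, 0.15, 0.14, 0.12)
  list(gene_probs = gp,
       pattern_probs = list(
         EGFR = c("p.Leu858Arg" = 0.0264),
         KRAS = c("p.Gly12Xaa" = 0.170, "p.Gly13Xaa" = 0.032)),
       feature_weights = c(missense = 0.73, nonsense = 0.06,
                           frameshift = 0.06, inframe = 0.01,
                           splice = 0.03, synonymous = 0.08,
                           intron = 0.02, other = 0.01),
       alteration_weights = c(SNP = 0.85, insertion = 0.07,
                              deletion = 0.08, MNP = 0, CNV = 0,
                              translocation = 0))
}

#' Two-site synthetic fixture
#'
#' Generates the pair of cohorts the model was validated on: site A, a
#' targeted-panel clinical cohort (n=114) with the full structural-type
#' mix including CNV and translocation rows, and site B, a WES-derived
#' cohort restricted to the same 49-gene panel (n=1060, SNP/INDEL only).
#' Surrogate keys of site B are offset so the two databases can be pooled
#' with [db_pool()].
#'
#' @param seed Integer seed driving both sites (site B derives its own).
#' @return List with `site_a` and `site_b` (`gcdm_db` handles).
#' @export
two_site_fixture <- function(seed = 1L) {
  a <- site_a_defaults()
  b <- site_b_defaults()
  list(
    site_a = generate_cohort(cohort_spec(
      114L, gene_probs = a$gene_probs, pattern_probs = a$pattern_probs,
      feature_weights = a$feature_weights,
      alteration_weights = a$alteration_weights,
      demographics = "ausom_like", seed = seed, id_offset = 0L,
      site_label = "site A (panel)")),
    site_b = generate_cohort(cohort_spec(
      1060L, gene_probs = b$gene_probs, pattern_probs = b$pattern_probs,
      feature_weights = b$feature_weights,
      alteration_weights = b$alteration_weights,
      demographics = "tcga_like", seed = seed + 1000003L,
      id_offset = 1000000L, site_label = "site B (WES-restricted)")))
}
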