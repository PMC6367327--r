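# Seeded synthetic cohort generator.
#
# The generator emulates the statistical structure the analysis stages
# assume — a dbNSFP-style variant table with twelve rank scores, per-clade
# conservation scores, gene metadata, a genes-x-tissues expression matrix,
# PPI degrees and per-epigenome chromatin-state tracks — with configurable
# *planted effects* so that every stage has a recoverable ground truth:
#
#   * conservation over-reliance: for selected tools the emitted score is a
#     mixture of the class-driven score and the site's vertebrate phastCons
#     value, creating detectable false-positive enrichment at highly
#     conserved benign positions;
#   * a per-site latent difficulty h (standard normal) that lowers every
#     tool's score at pathogenic sites (false negatives) and raises the
#     site's repressed-PolyComb propensity, creating the FN-vs-TP
#     chromatin-state contrast;
#   * quartet location/dispersion effects: alternative-allele scores at
#     pathogenic non-degenerate sites are drawn with higher location and
#     lower multiplicative dispersion than at benign sites (multiplicative
#     noise keeps the CV statistic exactly location-invariant, so the two
#     effects are separable);
#   * a per-gene latent importance z (standard normal) that inflates a
#     gene's share of pathogenic variants and its expression abundance,
#     tissue specificity and PPI degree.
#
# All randomness flows from the single mandatory seed; operations that can
# be regenerated independently (quartets, tracks) use documented fixed
# offsets from it.

#' Configuration of a synthetic cohort
#'
#' Builds the generator configuration with the package's study conditions
#' as defaults: 500 genes, about four variants per gene (~2000 variants),
#' site-group fractions 0.25 / 0.35 / 0.05 / 0.35
#' (pathogenic / benign / both / other), 53 tissues and 127 epigenomes.
#' `effects = "null"` zeroes every planted effect (type-I-error conditions)
#' while leaving the marginal distributions untouched.
#'
#' @param seed Mandatory integer seed; every random draw flows from it.
#' @param n_genes Number of genes.
#' @param mean_variants_per_gene Mean of the (1 + Poisson) per-gene variant
#'   count.
#' @param site_fractions Named fractions over the four site groups; must
#'   sum to 1.
#' @param dm_rate Probability that a pathogenic site is also an HGMD DM
#'   site.
#' @param back_mutation_rate Fraction of variants whose ancestral call
#'   equals the alternative allele.
#' @param n_tissues,n_epigenomes Panel sizes.
#' @param overreliance_tools Tools whose scores mix toward the conservation
#'   value.
#' @param overreliance_weight Mixture weight in \[0, 1) toward phastCons for
#'   those tools.
#' @param fn_link Logit-scale coefficient by which the site difficulty h
#'   depresses tool scores at pathogenic sites.
#' @param quartet_location_effect Location increase of pathogenic
#'   alternative-allele scores over the benign baseline 0.45.
#' @param quartet_dispersion_effect Reduction of the pathogenic
#'   multiplicative-noise SD below the benign baseline 0.35.
#' @param n_quartet_sites Number of non-degenerate sites emitted by
#'   [generate_quartets()].
#' @param gene_effect Coefficient of the gene latent z in the pathogenic
#'   class weight.
#' @param expr_effect,spec_effect,degree_effect Coefficients of z in the
#'   expression total, Dirichlet concentration (inverted) and PPI degree
#'   mean.
#' @param polycomb_base Logit-scale baseline of the repressed-PolyComb
#'   propensity.
#' @param polycomb_group_shift Logit-scale increase of that propensity at
#'   pathogenic/DM sites.
#' @param polycomb_fn_effect Logit-scale coefficient of the difficulty h in
#'   the propensity at pathogenic sites.
#' @param effects `"planted"` (defaults as given) or `"null"` (all effect
#'   parameters set to 0).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(seed,
                          n_genes = 500L,
                          mean_variants_per_gene = 4,
                          site_fractions = c(pathogenic = 0.25, benign = 0.35,
                                             both = 0.05, other = 0.35),
                          dm_rate = 0.6,
                          back_mutation_rate = 0.02,
                          n_tissues = 53L,
                          n_epigenomes = 127L,
                          overreliance_tools = c("SIFT", "MutationTaster", "DANN"),
                          overreliance_weight = 0.5,
                          fn_link = 0.9,
                          quartet_location_effect = 0.3,
                          quartet_dispersion_effect = 0.27,
                          n_quartet_sites = 1000L,
                          gene_effect = 0.8,
                          expr_effect = 0.8,
                          spec_effect = 0.8,
                          degree_effect = 1.2,
                          polycomb_base = -1.6,
                          polycomb_group_shift = 1.0,
                          polycomb_fn_effect = 1.0,
                          effects = c("planted", "null")) {
  effects <- match.arg(effects)
  if (missing(seed) || is.null(seed)) stop("config field 'seed' is mandatory")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("config field 'seed' must be a single integer")
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              mean_variants_per_gene = mean_variants_per_gene,
              site_fractions = site_fractions, dm_rate = dm_rate,
              back_mutation_rate = back_mutation_rate,
              n_tissues = as.integer(n_tissues),
              n_epigenomes = as.integer(n_epigenomes),
              overreliance_tools = overreliance_tools,
              overreliance_weight = overreliance_weight,
              fn_link = fn_link,
              quartet_location_effect = quartet_location_effect,
              quartet_dispersion_effect = quartet_dispersion_effect,
              n_quartet_sites = as.integer(n_quartet_sites),
              gene_effect = gene_effect, expr_effect = expr_effect,
              spec_effect = spec_effect, degree_effect = degree_effect,
              polycomb_base = polycomb_base,
              polycomb_group_shift = polycomb_group_shift,
              polycomb_fn_effect = polycomb_fn_effect,
              effects = effects)
  if (effects == "null") {
    cfg$overreliance_weight <- 0
    cfg$fn_link <- 0
    cfg$quartet_location_effect <- 0
    cfg$quartet_dispersion_effect <- 0
    cfg$gene_effect <- 0
    cfg$expr_effect <- 0
    cfg$spec_effect <- 0
    cfg$degree_effect <- 0
    cfg$polycomb_group_shift <- 0
    cfg$polycomb_fn_effect <- 0
  }
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) stop("invalid config field '", field, "': ", why)
  if (cfg$n_genes < 1) fail("n_genes", "must be >= 1")
  if (cfg$mean_variants_per_gene < 1) fail("mean_variants_per_gene", "must be >= 1")
  sf <- cfg$site_fractions
  if (!setequal(names(sf), c("pathogenic", "benign", "both", "other"))) {
    fail("site_fractions", "must name pathogenic, benign, both, other")
  }
  if (any(sf < 0) || abs(sum(sf) - 1) > 1e-8) fail("site_fractions", "must be >= 0 and sum to 1")
  for (field in c("dm_rate", "back_mutation_rate")) {
    if (cfg[[field]] < 0 || cfg[[field]] > 1) fail(field, "must lie in [0, 1]")
  }
  if (cfg$overreliance_weight < 0 || cfg$overreliance_weight >= 1) {
    fail("overreliance_weight", "must lie in [0, 1)")
  }
  bad_tools <- setdiff(cfg$overreliance_tools, prediction_tools())
  if (length(bad_tools)) fail("overreliance_tools", paste("unknown tool(s):",
                                                         paste(bad_tools, collapse = ", ")))
  if (cfg$n_tissues < 1) fail("n_tissues", "must be >= 1")
  if (cfg$n_epigenomes < 1) fail("n_epigenomes", "must be >= 1")
  if (cfg$quartet_dispersion_effect < 0 || cfg$quartet_dispersion_effect > 0.34) {
    fail("quartet_dispersion_effect", "must lie in [0, 0.34]")
  }
  if (cfg$quartet_location_effect < 0 || cfg$quartet_location_effect > 0.4) {
    fail("quartet_location_effect", "must lie in [0, 0.4]")
  }
  invisible(cfg)
}

# Tool-specific score-model parameters: per-class beta means and a
# concentration, spread over the panel so pairwise agreement is non-trivial.
tool_score_params <- function() {
  tools <- prediction_tools()
  k <- length(tools)
  data.table::data.table(
    tool = tools,
    mean_pathogenic = seq(0.62, 0.84, length.out = k),
    mean_benign = seq(0.36, 0.16, length.out = k),
    concentration = rep(c(5, 9, 14, 18), 3))
}

with_cohort_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% (.Machine$integer.max - 1L))
  force(code)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# phastCons per class: pathogenic sites concentrated high, benign a low/high
# mixture so both strata are populated.
draw_phastcons <- function(class, n) {
  high <- rbeta(n, 8, 2)
  low <- rbeta(n, 2, 8)
  p_high <- c(pathogenic = 0.8, benign = 0.3, both = 0.5, other = 0.45)[class]
  ifelse(runif(n) < p_high, high, low)
}

draw_phylop <- function(class, n) {
  mu <- c(pathogenic = 2.0, benign = 0.3, both = 1.0, other = 0.6)[class]
  rnorm(n, mu, 1.5)
}

#' Generate a synthetic cohort bundle
#'
#' Produces the full in-memory input bundle for the pipeline: a variant
#' table (alleles, clinical terms, HGMD classes, ancestral calls, per-clade
#' conservation scores and the twelve rank scores), gene metadata,
#' expression matrix, PPI degrees, chromatin-state tracks and the truth
#' tables recording every planted class and effect. Deterministic given the
#' config seed; [write_cohort()] serializes the bundle to disk in the
#' formats the package's readers consume.
#'
#' @param cfg A [cohort_config()].
#' @return A list of class `cohort_bundle` with elements `variants`,
#'   `genes`, `expression`, `degrees`, `tracks`, `truth_variants`,
#'   `truth_genes`, `config`.
#' @export
#' @examples
#' bundle <- generate_cohort(cohort_config(seed = 1, n_genes = 20))
#' nrow(bundle$variants)
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  validate_cohort_config(cfg)
  with_cohort_seed(cfg$seed, 0L, {
    ## --- genes -----------------------------------------------------------
    ng <- cfg$n_genes
    genes <- data.table::data.table(
      gene = sprintf("GENE%04d", seq_len(ng)),
      chrom = paste0("chr", (seq_len(ng) - 1L) %% 22L + 1L),
      z = rnorm(ng))
    genes[, gene_start := ((seq_len(ng) - 1L) %/% 22L) * 1000000L + 1000L]
    genes[, exon_length_bp := pmax(300L, as.integer(round(exp(rnorm(ng, log(2000), 0.6)))))]
    rate_kb <- pmax(5, rnorm(ng, 30, 12))  # SNV occurrence spread ~15-80/Kb
    genes[, n_polymorphic := rpois(ng, rate_kb * exon_length_bp / 1000)]

    # Expression: total abundance and tissue concentration tied to z.
    total <- exp(rnorm(ng, 3.0 + cfg$expr_effect * genes$z, 0.8))
    alpha <- exp(rnorm(ng, 0.5 - cfg$spec_effect * genes$z, 0.5))
    em <- matrix(rgamma(ng * cfg$n_tissues, shape = rep(alpha, cfg$n_tissues)),
                 nrow = ng)
    em <- em / rowSums(em) * total
    expression <- data.table::data.table(gene = genes$gene)
    tissue_names <- sprintf("tissue_%02d", seq_len(cfg$n_tissues))
    expression[, (tissue_names) := data.table::as.data.table(em)]

    degrees <- data.table::data.table(
      gene = genes$gene,
      degree = stats::rnbinom(ng, size = 4,
                              mu = exp(1.6 + cfg$degree_effect * genes$z)))

    ## --- variants --------------------------------------------------------
    n_per_gene <- 1L + rpois(ng, cfg$mean_variants_per_gene - 1)
    gene_idx <- rep(seq_len(ng), n_per_gene)
    nv <- length(gene_idx)
    within <- sequence(n_per_gene)
    variants <- data.table::data.table(
      gene = genes$gene[gene_idx],
      chrom = genes$chrom[gene_idx],
      pos = genes$gene_start[gene_idx] + within * 200L +
        sample(0:99, nv, replace = TRUE))

    # Site class: base fractions, pathogenic share inflated by the gene z.
    sf <- cfg$site_fractions
    w_path <- sf[["pathogenic"]] *
      exp(cfg$gene_effect * genes$z[gene_idx] - cfg$gene_effect^2 / 2)
    w <- cbind(pathogenic = w_path,
               benign = sf[["benign"]], both = sf[["both"]], other = sf[["other"]])
    w <- w / rowSums(w)
    u <- runif(nv)
    cum <- t(apply(w, 1, cumsum))
    class <- colnames(w)[1L + rowSums(u > cum)]

    ref <- sample(NUCLEOTIDES, nv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(NUCLEOTIDES, r), 1L), character(1))
    clinvar <- data.table::fcase(
      class == "pathogenic", sample(c("Pathogenic", "Likely pathogenic"), nv, TRUE,
                                    prob = c(0.7, 0.3)),
      class == "benign", sample(c("Benign", "Likely benign"), nv, TRUE,
                                prob = c(0.6, 0.4)),
      class == "both", "Pathogenic;Benign",
      default = NA_character_)
    hgmd <- rep("none", nv)
    is_path_like <- class %in% c("pathogenic", "both")
    hgmd[is_path_like] <- ifelse(runif(sum(is_path_like)) < cfg$dm_rate, "DM", "none")

    # Ancestral calls: mostly ref-ancestral, a few derived-to-ancestral
    # back mutations; 10% of calls low-confidence.
    is_back <- runif(nv) < cfg$back_mutation_rate
    ancestral <- ifelse(is_back, alt, ref)
    anc_conf <- ifelse(runif(nv) < 0.1, "low", "high")

    phast_vert <- draw_phastcons(class, nv)
    phast_mam <- clamp01(phast_vert + rnorm(nv, 0, 0.15))
    phast_pri <- clamp01(phast_vert + rnorm(nv, 0, 0.2))
    variants[, `:=`(ref = ref, alt = alt,
                    hgvs = paste0("c.", within * 3L, ref, ">", alt),
                    clinvar = clinvar, hgmd_class = hgmd,
                    ancestral_allele = ancestral, ancestral_confidence = anc_conf,
                    nondegenerate = runif(nv) < 0.7,
                    phastcons_vertebrate = phast_vert,
                    phastcons_mammal = phast_mam,
                    phastcons_primate = phast_pri,
                    phylop_vertebrate = draw_phylop(class, nv),
                    phylop_mammal = draw_phylop(class, nv) - 0.3,
                    phylop_primate = draw_phylop(class, nv) - 0.6)]

    # Tool scores. Latent difficulty h depresses scores at pathogenic-type
    # sites (false negatives); over-reliant tools mix toward phastCons.
    h <- rnorm(nv)
    params <- tool_score_params()
    class_mean <- function(tool_row, cls) {
      data.table::fcase(cls == "pathogenic", tool_row$mean_pathogenic,
                        cls == "benign", tool_row$mean_benign,
                        cls == "both", 0.5,
                        default = NA_real_)
    }
    for (i in seq_len(nrow(params))) {
      tool <- params$tool[i]
      m <- class_mean(params[i], class)
      # "other" sites: unlabeled mixture of the two marginals.
      other <- is.na(m)
      m[other] <- ifelse(runif(sum(other)) < 0.3,
                         params$mean_pathogenic[i], params$mean_benign[i])
      shift <- ifelse(is_path_like, cfg$fn_link * h, 0)
      m_eff <- stats::plogis(stats::qlogis(m) - shift)
      kap <- params$concentration[i]
      raw <- rbeta(nv, kap * m_eff, kap * (1 - m_eff))
      wmix <- if (tool %in% cfg$overreliance_tools) cfg$overreliance_weight else 0
      score <- (1 - wmix) * raw + wmix * phast_vert
      # Missingness: a small fraction of scores absent per tool.
      score[runif(nv) < 0.03] <- NA_real_
      variants[, (score_column(tool)) := score]
    }

    ## --- chromatin-state tracks -----------------------------------------
    is_dm_site <- hgmd == "DM"
    path_or_dm <- class == "pathogenic" | is_dm_site
    lin_rp <- cfg$polycomb_base + cfg$polycomb_group_shift * path_or_dm +
      cfg$polycomb_fn_effect * ifelse(path_or_dm, h, 0)
    p_rp <- stats::plogis(lin_rp)
    p_wk <- stats::plogis(lin_rp - 0.4)
    tracks <- draw_state_tracks(variants$chrom, variants$pos, p_rp, p_wk,
                                cfg$n_epigenomes)

    truth_variants <- data.table::data.table(
      chrom = variants$chrom, pos = variants$pos, gene = variants$gene,
      class = class, is_dm = is_dm_site, is_back_mutation = is_back,
      difficulty = h, p_reprpc = p_rp, p_reprpcwk = p_wk)
    truth_genes <- data.table::data.table(gene = genes$gene, z = genes$z)

    bundle <- list(
      variants = variants[],
      genes = genes[, .(gene, exon_length_bp, n_polymorphic)],
      expression = expression[],
      degrees = degrees[],
      tracks = tracks,
      truth_variants = truth_variants,
      truth_genes = truth_genes,
      config = cfg)
    class(bundle) <- "cohort_bundle"
    bundle
  })
}

# Per-site, per-epigenome state assignment (ReprPC / ReprPCWk / none,
# mutually exclusive) realized as non-overlapping BED-style intervals:
# variant positions are spaced >= 100 bp apart, intervals extend at most
# 40 bp, so per-epigenome tracks never overlap.
draw_state_tracks <- function(chrom, pos, p_rp, p_wk, n_epigenomes) {
  nv <- length(pos)
  epi_ids <- sprintf("E%03d", seq_len(n_epigenomes))
  u <- matrix(runif(nv * n_epigenomes), nrow = nv)
  cat_rp <- u < p_rp
  cat_wk <- !cat_rp & u < p_rp + p_wk * (1 - p_rp)
  idx_rp <- which(cat_rp, arr.ind = TRUE)
  idx_wk <- which(cat_wk, arr.ind = TRUE)
  build <- function(idx, state) {
    if (!nrow(idx)) return(NULL)
    site <- idx[, 1]
    data.table::data.table(
      epigenome = epi_ids[idx[, 2]],
      chrom = chrom[site],
      start = pos[site] - 1L - sample(0:20, nrow(idx), replace = TRUE),
      end = pos[site] + sample(0:20, nrow(idx), replace = TRUE),
      state = state)
  }
  out <- data.table::rbindlist(list(build(idx_rp, "ReprPC"),
                                    build(idx_wk, "ReprPCWk")))
  data.table::setorder(out, epigenome, chrom, start)
  out[]
}

#' Generate non-degenerate-site score quartets
#'
#' Emits per-site, per-tool alternative-allele score triples with their
#' truth class, feeding the four-allele statistics stage. Pathogenic-class
#' sites are drawn with higher location and lower multiplicative dispersion
#' than benign-class sites; because the noise is multiplicative and the
#' reference-allele convention fixes S_ref = 0, the CV statistic is exactly
#' invariant to the location parameter, so the two planted effects act on
#' max and CV separately. Uses the documented sub-stream `seed + 1`.
#'
#' @param cfg A [cohort_config()].
#' @return A `data.table` with one row per site and tool: `site_id`,
#'   `group`, `is_dm`, `ref`, `tool`, `phastcons_vertebrate`, and
#'   `score_A` ... `score_T` with the reference nucleotide's entry `NA`.
#' @export
generate_quartets <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_cohort_seed(cfg$seed, 1L, {
    ns <- cfg$n_quartet_sites
    sf <- cfg$site_fractions
    group <- sample(names(sf), ns, replace = TRUE, prob = sf)
    is_dm <- group %in% c("pathogenic", "both") & runif(ns) < cfg$dm_rate
    ref <- sample(NUCLEOTIDES, ns, replace = TRUE)
    phast <- draw_phastcons(group, ns)
    base_loc <- 0.45
    base_disp <- 0.35
    loc <- ifelse(group == "pathogenic", base_loc + cfg$quartet_location_effect,
           ifelse(group == "both", base_loc + cfg$quartet_location_effect / 2,
                  base_loc))
    disp <- ifelse(group == "pathogenic", base_disp - cfg$quartet_dispersion_effect,
            ifelse(group == "both", base_disp - cfg$quartet_dispersion_effect / 2,
                   base_disp))
    tools <- prediction_tools()
    rows <- lapply(seq_along(tools), function(ti) {
      # mild tool-specific location jitter, identical across classes
      tool_scale <- 0.9 + 0.2 * (ti - 1) / (length(tools) - 1)
      m <- clamp01(loc * tool_scale)
      delta <- matrix(rnorm(ns * 3, 0, disp), nrow = ns)
      alt_scores <- clamp01(m * (1 + delta))
      dt <- data.table::data.table(
        site_id = sprintf("S%05d", seq_len(ns)), group = group, is_dm = is_dm,
        ref = ref, tool = tools[ti], phastcons_vertebrate = phast,
        score_A = NA_real_, score_C = NA_real_, score_G = NA_real_,
        score_T = NA_real_)
      score_cols <- paste0("score_", NUCLEOTIDES)
      alt_of <- t(vapply(ref, function(r) setdiff(NUCLEOTIDES, r), character(3)))
      for (j in 1:3) {
        col_idx <- match(paste0("score_", alt_of[, j]), score_cols)
        for (nuc in seq_along(score_cols)) {
          sel <- col_idx == nuc
          if (any(sel)) data.table::set(dt, which(sel), score_cols[nuc],
                                        alt_scores[sel, j])
        }
      }
      dt
    })
    data.table::rbindlist(rows)
  })
}

#' Write a cohort bundle to disk
#'
#' Serializes a [generate_cohort()] bundle into the plain-text formats the
#' package's readers consume: `variants.tsv` (variant-table schema),
#' `genes.tsv`, `expression.tsv`, `degrees.tsv`, `state_tracks.tsv`
#' (concatenated track table with an `epigenome` column),
#' `truth_variants.tsv`, `truth_genes.tsv` and `config.yaml`.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_variant_table(bundle$variants, file.path(dir, "variants.tsv"))
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t",
                                          na = ".", quote = FALSE)
  fw(bundle$genes, "genes.tsv")
  fw(bundle$expression, "expression.tsv")
  fw(bundle$degrees, "degrees.tsv")
  fw(bundle$tracks, "state_tracks.tsv")
  fw(bundle$truth_variants, "truth_variants.tsv")
  fw(bundle$truth_genes, "truth_genes.tsv")
  cfg <- bundle$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
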