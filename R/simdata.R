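#' Pedigree specification for a backcross/F2 breeding population
#'
#' Describes a population of full-sib families derived from crosses between
#' two founder groups (a recurrent cultivar group and a donor group) through
#' F1 hybrids. Each family is one of three generation types: \code{"BCr"}
#' (backcross toward the donor, the rust-resistance source in the motivating
#' design), \code{"BCs"} (backcross toward the recurrent group) or
#' \code{"F2"} (selfed F1).
#'
#' The defaults describe 13 families of 15 plants each (195 individuals):
#' four BCr, five BCs and four F2 families, from 3 + 3 founders.
#'
#' @param n_families Number of full-sib families.
#' @param family_types Character vector of length \code{n_families}, each
#'   element one of \code{"BCr"}, \code{"BCs"}, \code{"F2"}.
#' @param individuals_per_family Plants genotyped per family.
#' @param n_catuai_parents Number of recurrent-group founders.
#' @param n_hdt_parents Number of donor-group founders.
#' @return An object of class \code{pedigree_spec}.
#' @export
pedigree_spec <- function(n_families = 13,
                          family_types = c("BCr", "BCs", "BCr", "BCs", "BCr",
                                           "BCs", "BCr", "BCs", "BCs",
                                           "F2", "F2", "F2", "F2"),
                          individuals_per_family = 15,
                          n_catuai_parents = 3,
                          n_hdt_parents = 3) {
  if (n_families < 1 || individuals_per_family < 1)
    stop("n_families and individuals_per_family must be positive", call. = FALSE)
  if (length(family_types) == 1 && n_families > 1)
    family_types <- rep(family_types, n_families)
  if (length(family_types) != n_families)
    stop("family_types must have one entry per family", call. = FALSE)
  if (!all(family_types %in% c("BCr", "BCs", "F2")))
    stop("family_types must be 'BCr', 'BCs' or 'F2'", call. = FALSE)
  if (n_catuai_parents < 1 || n_hdt_parents < 1)
    stop("at least one founder per group is required", call. = FALSE)
  structure(list(n_families = as.integer(n_families),
                 family_types = as.character(family_types),
                 individuals_per_family = as.integer(individuals_per_family),
                 n_catuai_parents = as.integer(n_catuai_parents),
                 n_hdt_parents = as.integer(n_hdt_parents)),
            class = "pedigree_spec")
}

#' Simulate the pedigree of a backcross/F2 population
#'
#' Builds the crossing structure: founders of the two groups, F1 hybrids
#' (one Catuai-group x one donor-group founder each), and the families.
#' A BCr family is F1 x donor founder, a BCs family is F1 x Catuai-group
#' founder, and an F2 family is a selfed F1. Founder pairs for the hybrids
#' and the backcross parents are drawn at random but reproducibly from the
#' seed.
#'
#' @param spec A \code{\link{pedigree_spec}}.
#' @param seed Integer seed; same seed and spec give an identical pedigree.
#' @return A \code{pedigree} object: list with \code{individuals} (data frame
#'   of id, family, pop_type), \code{families} (data frame of family, type,
#'   parent1, parent2) and \code{founders} (character vector of founder ids).
#' @export
simulate_pedigree <- function(spec = pedigree_spec(), seed = 1L) {
  stopifnot(inherits(spec, "pedigree_spec"))
  set.seed(as.integer(seed))
  cat_ids <- paste0("C", seq_len(spec$n_catuai_parents))
  hdt_ids <- paste0("HdT", seq_len(spec$n_hdt_parents))

  # one F1 hybrid per family lineage; hybrids may be shared is not required,
  # so each family gets its own hybrid from a random founder pair
  fam <- data.frame(family = paste0("fam", seq_len(spec$n_families)),
                    type = spec$family_types,
                    stringsAsFactors = FALSE)
  fam$hybrid_cat <- sample(cat_ids, spec$n_families, replace = TRUE)
  fam$hybrid_hdt <- sample(hdt_ids, spec$n_families, replace = TRUE)
  fam$parent1 <- paste0("H", seq_len(spec$n_families))
  fam$parent2 <- ifelse(fam$type == "BCr",
                        sample(hdt_ids, spec$n_families, replace = TRUE),
                 ifelse(fam$type == "BCs",
                        sample(cat_ids, spec$n_families, replace = TRUE),
                        fam$parent1))  # F2: selfed hybrid

  n <- spec$n_families * spec$individuals_per_family
  ind <- data.frame(
    id = sprintf("ind%03d", seq_len(n)),
    family = rep(fam$family, each = spec$individuals_per_family),
    pop_type = rep(fam$type, each = spec$individuals_per_family),
    stringsAsFactors = FALSE)

  structure(list(individuals = ind, families = fam,
                 founders = c(cat_ids, hdt_ids), spec = spec, seed = seed),
            class = "pedigree")
}

#' Simulate a SNP marker panel by gene dropping through the pedigree
#'
#' Founder haplotypes are drawn marker-by-marker from a minor-allele-frequency
#' distribution (each founder allele is a Bernoulli draw, so founders may be
#' heterozygous). Offspring dosages are produced by independent Mendelian
#' segregation per marker: each gamete carries the counted allele with
#' probability dosage/2 of the transmitting parent. Markers are unlinked; the
#' downstream analyses never use map distances.
#'
#' Two data-quality phenomena of allopolyploid SNP panels are emulated
#' directly: a fraction of markers is forced invariant across all individuals
#' ("false SNPs" between homeologous subgenome copies, here set heterozygous
#' in everyone), and missing calls are injected completely at random.
#'
#' @param pedigree A \code{pedigree} from \code{\link{simulate_pedigree}}.
#' @param n_markers Number of SNPs.
#' @param founder_maf A function \code{(m)} returning \code{m} founder allele
#'   frequencies in (0, 1); default uniform on \code{[0.1, 0.5]}.
#' @param missing_rate Probability a call is missing.
#' @param invariant_fraction Fraction of markers forced invariant
#'   (\code{floor(invariant_fraction * n_markers)} markers).
#' @param chromosomes Character vector of chromosome group labels.
#' @param chrom_weights Sampling weights for assigning markers to groups.
#' @param seed Integer seed.
#' @return A \code{marker_panel}: list with \code{genotypes} (individuals x
#'   markers integer matrix, entries 0/1/2/NA, dimnames set), \code{map}
#'   (data frame marker_id, chromosome), \code{invariant_markers}
#'   (character ids of the forced-invariant markers), and the
#'   \code{founder_dosages} and \code{hybrid_dosages} (markers x parents,
#'   before invariant forcing and missingness) that gene dropping used —
#'   kept so Mendelian consistency can be audited.
#' @export
simulate_genotypes <- function(pedigree, n_markers = 2000,
                               founder_maf = function(m) stats::runif(m, 0.1, 0.5),
                               missing_rate = 0.02,
                               invariant_fraction = 0.02,
                               chromosomes = c(paste0("chr", 1:11), "chr0", "UNIGENE"),
                               chrom_weights = c(rep(1, 11), 0.6, 0.05),
                               seed = 1L) {
  stopifnot(inherits(pedigree, "pedigree"))
  if (n_markers < 1) stop("n_markers must be >= 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1 ||
      invariant_fraction < 0 || invariant_fraction > 1)
    stop("missing_rate and invariant_fraction must be in [0, 1]", call. = FALSE)
  if (length(chrom_weights) != length(chromosomes))
    stop("chrom_weights must match chromosomes", call. = FALSE)
  set.seed(as.integer(seed))

  p <- founder_maf(n_markers)
  if (any(p <= 0) || any(p >= 1))
    stop("founder_maf must return frequencies strictly inside (0, 1)", call. = FALSE)

  founders <- pedigree$founders
  # founder dosages: two independent allele draws per founder per marker
  fdos <- sapply(founders, function(f)
    stats::rbinom(n_markers, 2L, p), simplify = "array")  # markers x founders
  colnames(fdos) <- founders

  # one gamete from a parent with dosage d carries the allele w.p. d/2
  gamete <- function(dos) stats::rbinom(length(dos), 1L, dos / 2)

  fam <- pedigree$families
  hyb <- matrix(0L, n_markers, nrow(fam))  # hybrid dosage per family lineage
  for (k in seq_len(nrow(fam)))
    hyb[, k] <- gamete(fdos[, fam$hybrid_cat[k]]) + gamete(fdos[, fam$hybrid_hdt[k]])

  ind <- pedigree$individuals
  G <- matrix(0L, nrow(ind), n_markers,
              dimnames = list(ind$id, sprintf("snp%05d", seq_len(n_markers))))
  for (k in seq_len(nrow(fam))) {
    rows <- which(ind$family == fam$family[k])
    other <- if (fam$type[k] == "F2") hyb[, k] else fdos[, fam$parent2[k]]
    for (r in rows) G[r, ] <- gamete(hyb[, k]) + gamete(other)
  }

  n_inv <- floor(invariant_fraction * n_markers)
  inv_idx <- if (n_inv > 0) sample.int(n_markers, n_inv) else integer(0)
  if (n_inv > 0) G[, inv_idx] <- 1L  # heterozygous in everyone: zero variance

  if (missing_rate > 0) {
    miss <- stats::runif(length(G)) < missing_rate
    G[miss] <- NA_integer_
  }

  map <- data.frame(
    marker_id = colnames(G),
    chromosome = sample(chromosomes, n_markers, replace = TRUE,
                        prob = chrom_weights / sum(chrom_weights)),
    stringsAsFactors = FALSE)

  colnames(hyb) <- fam$family
  rownames(hyb) <- rownames(fdos) <- colnames(G)
  structure(list(genotypes = G, map = map,
                 invariant_markers = colnames(G)[inv_idx],
                 founder_dosages = fdos, hybrid_dosages = hyb),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "markers;",
      length(unique(x$map$chromosome)), "chromosome groups\n")
  invisible(x)
}

#' Trait specification for the phenotype simulator
#'
#' @param name Trait name.
#' @param type \code{"continuous"} or \code{"score"}.
#' @param score_levels Number of ordered score classes (score traits only).
#' @param variance_components Named numeric vector with elements
#'   \code{genotype}, \code{permanent}, \code{poptype}, \code{plot},
#'   \code{interaction}, \code{residual} (nonnegative; at least one positive).
#' @param n_qtl Number of causal markers sampled from the panel.
#' @param year_means One fixed mean per year.
#' @return A \code{trait_spec} object.
#' @export
trait_spec <- function(name, type = c("continuous", "score"), score_levels = 5L,
                       variance_components = c(genotype = 0.4, permanent = 0,
                                               poptype = 0.02, plot = 0.05,
                                               interaction = 0.1, residual = 0.43),
                       n_qtl = 200L, year_means = c(10, 11, 12)) {
  type <- match.arg(type)
  need <- c("genotype", "permanent", "poptype", "plot", "interaction", "residual")
  if (!all(need %in% names(variance_components)))
    stop("variance_components must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  vc <- variance_components[need]
  if (any(vc < 0)) stop("variances must be nonnegative", call. = FALSE)
  if (all(vc == 0)) stop("at least one variance must be positive", call. = FALSE)
  if (type == "score" && score_levels < 2)
    stop("score traits need score_levels >= 2", call. = FALSE)
  structure(list(name = name, type = type,
                 score_levels = as.integer(score_levels),
                 variance_components = vc, n_qtl = as.integer(n_qtl),
                 year_means = as.numeric(year_means)),
            class = "trait_spec")
}

#' Default trait set emulating an 18-trait perennial evaluation
#'
#' Eleven continuous traits (yield, leaf and branch dimensions, node and
#' fruit counts, plant height, canopy and stem diameter) and seven score
#' traits (fruit size 1-3, maturation uniformity 1-4, maturation cycle and
#' the two disease incidences plus leaf-miner on 1-5, vigor 1-10). Each
#' trait's genotype variance is its individual narrow-sense heritability on
#' a unit total-variance scale, spanning the low-to-moderate range typical
#' of complex agronomic traits (0.16-0.46), with QTL counts from a few
#' hundred up to several thousand.
#'
#' @param n_years Number of evaluation years (year means are spaced mildly).
#' @return Named list of \code{\link{trait_spec}} objects.
#' @export
default_trait_specs <- function(n_years = 3) {
  def <- list(
    #         type        levels h2    nqtl
    Y   = list("continuous", 0L, 0.26,  751L),
    LL  = list("continuous", 0L, 0.29, 3981L),
    LW  = list("continuous", 0L, 0.32, 5000L),
    BL  = list("continuous", 0L, 0.41,  244L),
    NRN = list("continuous", 0L, 0.23, 4000L),
    NVN = list("continuous", 0L, 0.46,  199L),
    NF  = list("continuous", 0L, 0.34, 1157L),
    FV  = list("continuous", 0L, 0.25, 1081L),
    PH  = list("continuous", 0L, 0.46,  202L),
    CD  = list("continuous", 0L, 0.45,  149L),
    SD  = list("continuous", 0L, 0.16, 1658L),
    RFS = list("score",      3L, 0.36,  394L),
    MU  = list("score",      4L, 0.28, 5000L),
    MC  = list("score",      5L, 0.31, 1313L),
    Rus = list("score",      5L, 0.31,  221L),
    Cer = list("score",      5L, 0.44,  304L),
    LM  = list("score",      5L, 0.30,  476L),
    Vig = list("score",     10L, 0.34,  440L))
  out <- lapply(names(def), function(nm) {
    d <- def[[nm]]
    h2 <- d[[3]]
    rest <- 1 - h2 - 0.02 - 0.05  # poptype + plot fixed small
    trait_spec(nm, type = d[[1]], score_levels = max(d[[2]], 2L),
               variance_components = c(genotype = h2, permanent = 0,
                                       poptype = 0.02, plot = 0.05,
                                       interaction = rest / 4,
                                       residual = 3 * rest / 4),
               n_qtl = d[[4]],
               year_means = 10 + seq_len(n_years) - 1)
  })
  names(out) <- names(def)
  out
}

#' Simulate multi-year phenotypes over a marker panel
#'
#' For each trait, \code{n_qtl} causal markers are sampled from the panel and
#' standard-normal effects drawn, then rescaled so the realized in-sample
#' variance of the genetic values equals the specified genotype variance
#' exactly. Permanent-plant, population-type, plot, family-by-year
#' interaction and residual deviations are drawn independently with their
#' specified variances; year means are added. Score traits threshold the
#' latent value into \code{score_levels} ordered classes at equally spaced
#' quantile cut points (approximately equal occupancy).
#'
#' Plots are field blocks that cross the families: the k-th plant of every
#' family shares a block (the repetition layout of a randomized block
#' trial), \code{plants_per_plot} consecutive repetitions wide, and a plant
#' stays in its plot across years. The interaction effect is indexed by
#' family x year, which keeps it estimable with single-plant genotypes.
#'
#' @param panel A \code{marker_panel}; all individuals must be genotyped.
#' @param pedigree The matching \code{pedigree}.
#' @param traits List of \code{\link{trait_spec}}s.
#' @param n_years Number of years of records per plant.
#' @param plants_per_plot Plants per plot within family.
#' @param seed Integer seed.
#' @return List with \code{phenotypes} (long data frame: individual, family,
#'   pop_type, plot, year, trait, value) and \code{truth} (per-trait list of
#'   true breeding values, QTL ids/effects, and realized variance shares).
#' @export
simulate_phenotypes <- function(panel, pedigree, traits = default_trait_specs(),
                                n_years = 3, plants_per_plot = 1, seed = 1L) {
  stopifnot(inherits(panel, "marker_panel"), inherits(pedigree, "pedigree"))
  ind <- pedigree$individuals
  if (!all(ind$id %in% rownames(panel$genotypes)))
    stop("all individuals must be genotyped", call. = FALSE)
  set.seed(as.integer(seed))

  W <- impute_missing(panel$genotypes)
  n <- nrow(ind)

  # field blocks cross the families: the k-th plants of every family share a
  # plot (the "repetition" layout of a randomized block trial); a plant keeps
  # its plot across years
  within <- stats::ave(seq_len(n), ind$family, FUN = seq_along)
  plot_of <- paste0("block", ceiling(within / plants_per_plot))

  years <- seq_len(n_years)
  base <- data.frame(individual = rep(ind$id, times = n_years),
                     family = rep(ind$family, times = n_years),
                     pop_type = rep(ind$pop_type, times = n_years),
                     plot = rep(plot_of, times = n_years),
                     year = rep(years, each = n),
                     stringsAsFactors = FALSE)

  pheno <- list(); truth <- list()
  for (tr in traits) {
    vc <- tr$variance_components
    if (tr$n_qtl > ncol(W))
      stop("n_qtl exceeds number of markers for trait ", tr$name, call. = FALSE)
    if (length(tr$year_means) != n_years)
      stop("year_means must have one value per year for trait ", tr$name,
           call. = FALSE)

    # genetic values: QTL effects rescaled to hit sigma_g^2 in-sample
    qtl <- sample.int(ncol(W), tr$n_qtl)
    eff <- stats::rnorm(tr$n_qtl)
    g <- drop(W[ind$id, qtl, drop = FALSE] %*% eff)
    vg <- stats::var(g)
    if (vc[["genotype"]] > 0 && vg > 0) {
      sc <- sqrt(vc[["genotype"]] / vg)
      eff <- eff * sc; g <- g * sc
    } else {
      eff <- eff * 0; g <- g * 0
    }
    g <- g - mean(g)

    draw <- function(levels, v)
      if (v > 0) stats::setNames(stats::rnorm(length(levels), 0, sqrt(v)), levels)
      else stats::setNames(numeric(length(levels)), levels)
    p_eff <- draw(ind$id, vc[["permanent"]])
    r_eff <- draw(unique(ind$pop_type), vc[["poptype"]])
    b_eff <- draw(unique(plot_of), vc[["plot"]])
    iy_lv <- as.vector(outer(unique(ind$family), years, paste, sep = ":"))
    i_eff <- draw(iy_lv, vc[["interaction"]])

    lat <- tr$year_means[base$year] +
      g[match(base$individual, ind$id)] +
      p_eff[base$individual] +
      r_eff[base$pop_type] +
      b_eff[base$plot] +
      i_eff[paste(base$family, base$year, sep = ":")] +
      stats::rnorm(nrow(base), 0, sqrt(vc[["residual"]]))

    value <- if (tr$type == "score") {
      cuts <- stats::quantile(lat, probs = seq_len(tr$score_levels - 1) /
                                tr$score_levels)
      as.numeric(findInterval(lat, cuts) + 1L)
    } else lat

    pheno[[tr$name]] <- cbind(base, trait = tr$name, value = value,
                              stringsAsFactors = FALSE)
    truth[[tr$name]] <- list(
      true_breeding_values = stats::setNames(g, ind$id),
      true_qtl_ids = colnames(W)[qtl],
      true_qtl_effects = eff,
      realized_h2 = vc[["genotype"]] / sum(vc))
  }

  list(phenotypes = do.call(rbind, c(pheno, list(make.row.names = FALSE))),
       truth = truth)
}

#' Write a marker panel to tab-separated text files
#'
#' @param panel A \code{marker_panel}.
#' @param genotype_file Path for the genotype matrix (first column
#'   \code{id}, then one column per marker, NA for missing).
#' @param map_file Path for the marker map (marker_id, chromosome).
#' @export
write_panel <- function(panel, genotype_file, map_file) {
  df <- data.frame(id = rownames(panel$genotypes), panel$genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, genotype_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$map, map_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(panel)
}

#' Read a marker panel written by \code{\link{write_panel}}
#'
#' @param genotype_file,map_file Paths written by \code{\link{write_panel}}.
#' @return A \code{marker_panel}.
#' @export
read_panel <- function(genotype_file, map_file) {
  df <- utils::read.delim(genotype_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- df[[1]]
  map <- utils::read.delim(map_file, stringsAsFactors = FALSE)
  bad <- setdiff(stats::na.omit(unique(as.vector(G))), 0:2)
  if (length(bad)) stop("genotype values must be 0/1/2/NA", call. = FALSE)
  if (!identical(map$marker_id, colnames(G)))
    stop("map does not match genotype columns", call. = FALSE)
  structure(list(genotypes = G, map = map, invariant_markers = character(0)),
            class = "marker_panel")
}

#' Simulate records directly from the phenotypic mixed model
#'
#' Draws every random effect independently from its specified variance
#' (genotype, permanent, poptype, plot, family-by-year interaction,
#' residual) over the standard layout of families, plots and years — the
#' generative counterpart of the model \code{\link{reml_fit}} estimates,
#' used for parameter-recovery checks. Unlike the gene-dropping simulator,
#' genotype effects here are i.i.d., so there is no genetic relatedness
#' for the grouping factors to absorb.
#'
#' @param variance_components Named vector over genotype, permanent,
#'   poptype, plot, interaction, residual.
#' @param n_genotypes,n_families,n_years,plants_per_plot Layout sizes.
#' @param year_means Fixed mean per year.
#' @param seed Integer seed.
#' @return Long-format phenotype data frame (trait \code{"sim"}).
#' @export
simulate_lmm_records <- function(variance_components,
                                 n_genotypes = 195L, n_families = 13L,
                                 n_years = 3L, plants_per_plot = 1L,
                                 year_means = c(10, 11, 12), seed = 1L) {
  vc <- variance_components[canonical_components]
  if (any(is.na(vc))) stop("all six components are required", call. = FALSE)
  set.seed(as.integer(seed))
  per_fam <- ceiling(n_genotypes / n_families)
  ind <- sprintf("ind%03d", seq_len(n_genotypes))
  fam <- paste0("fam", rep(seq_len(n_families), each = per_fam)[seq_len(n_genotypes)])
  ptype <- c("BCr", "BCs", "F2")[(as.integer(factor(fam, unique(fam))) - 1L) %% 3L + 1L]
  within <- stats::ave(seq_along(ind), fam, FUN = seq_along)
  plt <- paste0("block", ceiling(within / plants_per_plot))

  draw <- function(levels, v)
    stats::setNames(if (v > 0) stats::rnorm(length(unique(levels)), 0, sqrt(v))
                    else numeric(length(unique(levels))), unique(levels))
  g <- draw(ind, vc[["genotype"]]); p <- draw(ind, vc[["permanent"]])
  r <- draw(ptype, vc[["poptype"]]); b <- draw(plt, vc[["plot"]])
  years <- seq_len(n_years)
  iy <- as.vector(outer(unique(fam), years, paste, sep = ":"))
  i_eff <- draw(iy, vc[["interaction"]])

  d <- data.frame(individual = rep(ind, n_years), family = rep(fam, n_years),
                  pop_type = rep(ptype, n_years), plot = rep(plt, n_years),
                  year = rep(years, each = n_genotypes),
                  trait = "sim", stringsAsFactors = FALSE)
  d$value <- year_means[d$year] + g[d$individual] + p[d$individual] +
    r[d$pop_type] + b[d$plot] + i_eff[paste(d$family, d$year, sep = ":")] +
    stats::rnorm(nrow(d), 0, sqrt(vc[["residual"]]))
  d
}
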