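#' Configuration for a synthetic moss-microbiome study
#'
#' Builds the parameter set for [generateStudy()]. The defaults emulate the
#' sampling design of a two-peatland-system survey: two systems
#' (`amb` = Amblystegiaceae fens, `sph` = Sphagnum bogs), two areas per
#' system, three subsites per area, three moss plants per subsite each
#' yielding two endophyte technical-replicate libraries plus one epiphyte
#' library, and two reference libraries (one sediment, one vascular plant)
#' per subsite. Ground truth is planted: a shared core OTU set present in
#' both systems at high abundance (an order of magnitude more abundant in
#' Sphagnum than in Amblystegiaceae), system-specific OTU sets absent outside
#' their own system, and endophyte-enriched OTUs whose abundance is
#' multiplied by `endophyte_fold` in endophyte-fraction libraries.
#'
#' Compositions follow a log-linear model (per-OTU baseline + moss species
#' effect + covariate slopes + hydrology effect + endophyte enrichment) with
#' Dirichlet-multinomial noise: a plant-level latent composition drawn from a
#' Dirichlet with concentration `dispersion`, small replicate-level Dirichlet
#' jitter with concentration `replicate_concentration`, and multinomial
#' counts at a uniform-random library size. Covariates are generated
#' correlated with the system (pH 3.3-5.0 in sph vs 5.8-7.0 in amb, CH4
#' higher in sph) so the field-realistic collinearity between moss taxon and
#' environment is reproduced.
#'
#' @param n_areas_per_system,n_subsites_per_area,n_plants_per_subsite,n_reference_samples_per_subsite
#'   design counts (defaults 2, 3, 3, 2).
#' @param n_otus_total total number of OTUs (default 2000).
#' @param n_core_shared number of planted shared-core OTUs (default 50).
#' @param n_system_specific_per_system planted system-specific OTUs per
#'   system (default 300).
#' @param n_endophyte_enriched planted endophyte-enriched OTUs (default 25).
#' @param core_mean_relabund named numeric: mean unnormalised weight of each
#'   core OTU per system (defaults sph 0.02, amb 0.002).
#' @param endophyte_fold multiplicative enrichment of planted endophyte OTUs
#'   in endophyte libraries (default 8; 1 = null).
#' @param library_size_range integer range of library sizes
#'   (default 5000-50000).
#' @param dispersion Dirichlet concentration of the plant/sample-level draw
#'   (default 1000; larger = less overdispersion).
#' @param replicate_concentration Dirichlet concentration of the
#'   within-plant library-level jitter (default 1e6, i.e. small technical
#'   noise on top of the shared plant composition).
#' @param covariate_effects named numeric log-abundance slopes per
#'   standardized covariate (defaults pH 0.5, temperature 0.3, ch4 0.3).
#' @param species_effect_sd standard deviation of per-(species, OTU)
#'   log-abundance effects (default 1; 0 = no plant-taxon structure).
#' @param hydrology_effect standard deviation of per-OTU submerged-vs-emerged
#'   log-abundance effects (default 0.3).
#' @param seed integer RNG seed.
#' @return a `StudyConfig` (a validated named list).
#' @export
studyConfig <- function(n_areas_per_system = 2L,
                        n_subsites_per_area = 3L,
                        n_plants_per_subsite = 3L,
                        n_reference_samples_per_subsite = 2L,
                        n_otus_total = 2000L,
                        n_core_shared = 50L,
                        n_system_specific_per_system = 300L,
                        n_endophyte_enriched = 25L,
                        core_mean_relabund = c(sph = 0.02, amb = 0.002),
                        endophyte_fold = 8,
                        library_size_range = c(5000L, 50000L),
                        dispersion = 1000,
                        replicate_concentration = 1e6,
                        covariate_effects = c(pH = 0.5, temperature = 0.3, ch4 = 0.3),
                        species_effect_sd = 1,
                        hydrology_effect = 0.3,
                        seed = 1L) {
  cfg <- list(
    n_areas_per_system = as.integer(n_areas_per_system),
    n_subsites_per_area = as.integer(n_subsites_per_area),
    n_plants_per_subsite = as.integer(n_plants_per_subsite),
    n_reference_samples_per_subsite = as.integer(n_reference_samples_per_subsite),
    n_otus_total = as.integer(n_otus_total),
    n_core_shared = as.integer(n_core_shared),
    n_system_specific_per_system = as.integer(n_system_specific_per_system),
    n_endophyte_enriched = as.integer(n_endophyte_enriched),
    core_mean_relabund = core_mean_relabund,
    endophyte_fold = endophyte_fold,
    library_size_range = as.integer(library_size_range),
    dispersion = dispersion,
    replicate_concentration = replicate_concentration,
    covariate_effects = covariate_effects,
    species_effect_sd = species_effect_sd,
    hydrology_effect = hydrology_effect,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_areas_per_system < 1L || n_subsites_per_area < 1L ||
        n_plants_per_subsite < 1L || n_otus_total < 1L) {
      stop("design counts must be >= 1")
    }
    planted <- n_core_shared + 2L * n_system_specific_per_system + n_endophyte_enriched
    if (planted > n_otus_total) {
      stop("planted OTU sets (", planted, ") exceed n_otus_total (", n_otus_total, ")")
    }
    if (endophyte_fold < 1) stop("endophyte_fold must be >= 1")
    if (length(library_size_range) != 2L || library_size_range[1] < 1L ||
        library_size_range[2] < library_size_range[1]) {
      stop("invalid library_size_range")
    }
    if (!all(c("sph", "amb") %in% names(core_mean_relabund))) {
      stop("core_mean_relabund needs 'sph' and 'amb' entries")
    }
    if (dispersion <= 0 || replicate_concentration <= 0) {
      stop("Dirichlet concentrations must be positive")
    }
  })
  class(cfg) <- c("StudyConfig", "list")
  cfg
}

.speciesPools <- list(
  amb = c("Amblystegiaceae_mix", "Scorpidium_scorpioides", "Drepanocladus_revolvens"),
  sph = c("Sphagnum_riparium", "Sphagnum_fallax", "Sphagnum_magellanicum",
          "Sphagnum_lindbergii")
)

.taxPool <- c(
  "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rhodospirillales; f__Acetobacteraceae",
  "k__Bacteria; p__Acidobacteria; c__Acidobacteriia; o__Acidobacteriales; f__Acidobacteriaceae",
  "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rhizobiales; f__Hyphomicrobiaceae",
  "k__Bacteria; p__Proteobacteria; c__Betaproteobacteria; o__Burkholderiales; f__Comamonadaceae",
  "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Sphingomonadales; f__Sphingomonadaceae",
  "k__Bacteria; p__Actinobacteria; c__Acidimicrobiia; o__Acidimicrobiales; f__C111",
  "k__Bacteria; p__Cyanobacteria; c__Synechococcophycideae; o__Pseudanabaenales; f__Pseudanabaenaceae",
  "k__Bacteria; p__Verrucomicrobia; c__Verrucomicrobiae; o__Verrucomicrobiales; f__Verrucomicrobiaceae"
)

#' Generate a synthetic study
#'
#' Draws an OTU table, its sample metadata, and the planted ground truth from
#' a [studyConfig()]. Deterministic under the config seed (the caller's RNG
#' state is preserved).
#'
#' @param config a `StudyConfig`.
#' @return list with elements `table` ([OtuTable-class]), `metadata`
#'   (`data.frame`), and `truth` (list: `core_ids`,
#'   `system_specific_ids` per system, `endophyte_ids`, `expected`
#'   per-sample expected composition matrix, `covariates`).
#' @export
generateStudy <- function(config = studyConfig()) {
  stopifnot(inherits(config, "StudyConfig"))
  withr::with_seed(config$seed, .generateStudyImpl(config))
}

.generateStudyImpl <- function(cfg) {
  nO <- cfg$n_otus_total
  otu_ids <- sprintf("OTU_%05d", seq_len(nO))
  idx <- seq_len(nO)
  core <- idx[seq_len(cfg$n_core_shared)]
  off <- cfg$n_core_shared
  ambSpec <- idx[off + seq_len(cfg$n_system_specific_per_system)]
  off <- off + cfg$n_system_specific_per_system
  sphSpec <- idx[off + seq_len(cfg$n_system_specific_per_system)]
  off <- off + cfg$n_system_specific_per_system
  endo <- idx[off + seq_len(cfg$n_endophyte_enriched)]
  bg <- setdiff(idx, c(core, ambSpec, sphSpec, endo))

  taxonomy <- sample(.taxPool, nO, replace = TRUE)
  taxonomy[core] <- rep(.taxPool[1:2], length.out = length(core))
  taxonomy <- paste0(taxonomy, "; g__; s__")

  ## ---- sample design -------------------------------------------------
  systems <- c("amb", "sph")
  areaNames <- list(
    amb = if (cfg$n_areas_per_system == 2L) c("SV", "SA") else
      paste0("ambA", seq_len(cfg$n_areas_per_system)),
    sph = if (cfg$n_areas_per_system == 2L) c("NEI", "MUE") else
      paste0("sphA", seq_len(cfg$n_areas_per_system))
  )
  rows <- list()
  for (sys in systems) {
    pool <- .speciesPools[[sys]]
    for (ar in areaNames[[sys]]) {
      tempMean <- runif(1, 8, 16)
      for (si in seq_len(cfg$n_subsites_per_area)) {
        sub <- paste0(ar, "_s", si)
        species <- sample(pool, 1L)
        pH_sub <- if (sys == "sph") runif(1, 3.3, 5.0) else runif(1, 5.8, 7.0)
        ch4_sub <- exp(rnorm(1, log(if (sys == "sph") 80 else 20), 0.8))
        temp_sub <- tempMean + rnorm(1, 0, 1.5)
        for (pl in seq_len(cfg$n_plants_per_subsite)) {
          unit <- paste(sys, sub, paste0("p", pl), sep = "_")
          hyd <- sample(c("submerged", "emerged"), 1L)
          pH <- min(14, max(0, pH_sub + rnorm(1, 0, 0.1)))
          for (rep in 1:2) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = paste0(unit, "_endo", rep), system = sys, area = ar,
              subsite = sub, plant_label = species, sample_class = "moss",
              fraction = "endophyte", plant_unit = unit, hydrology = hyd,
              pH = pH, temperature = temp_sub, ch4 = ch4_sub,
              stringsAsFactors = FALSE)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = paste0(unit, "_epi"), system = sys, area = ar,
            subsite = sub, plant_label = species, sample_class = "moss",
            fraction = "epiphyte", plant_unit = unit, hydrology = hyd,
            pH = pH, temperature = temp_sub, ch4 = ch4_sub,
            stringsAsFactors = FALSE)
        }
        for (rf in seq_len(cfg$n_reference_samples_per_subsite)) {
          isSed <- rf %% 2L == 1L
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = paste(sys, sub, paste0("ref", rf), sep = "_"),
            system = sys, area = ar, subsite = sub,
            plant_label = if (isSed) "sediment" else
              sample(c("Carex_sp", "Eriophorum_sp"), 1L),
            sample_class = if (isSed) "sediment" else "vascular",
            fraction = "reference", plant_unit = NA_character_,
            hydrology = sample(c("submerged", "emerged"), 1L),
            pH = min(14, max(0, pH_sub + rnorm(1, 0, 0.15))),
            temperature = temp_sub, ch4 = ch4_sub,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  md <- do.call(rbind, rows)
  rownames(md) <- md$sample_id
  nS <- nrow(md)

  ## ---- per-OTU baselines ---------------------------------------------
  baseW <- matrix(0, nO, 2, dimnames = list(otu_ids, systems))
  coreJit <- exp(rnorm(length(core), 0, 0.3))
  baseW[core, "amb"] <- cfg$core_mean_relabund[["amb"]] * coreJit
  baseW[core, "sph"] <- cfg$core_mean_relabund[["sph"]] * coreJit
  baseW[ambSpec, "amb"] <- exp(rnorm(length(ambSpec), log(0.001), 0.7))
  baseW[sphSpec, "sph"] <- exp(rnorm(length(sphSpec), log(0.001), 0.7))
  endoBase <- exp(rnorm(length(endo), log(0.002), 0.3))
  baseW[endo, ] <- cbind(endoBase, endoBase)
  bgBase <- exp(rnorm(length(bg), log(5e-4), 1.2))
  baseW[bg, ] <- cbind(bgBase, bgBase)

  ## fixed random loadings for species, hydrology and covariate effects.
  ## Planted core OTUs are host-generalists by construction (that is what
  ## makes them a core): the loadings do not act on them, so their abundance
  ## varies only through the system baseline and the Dirichlet noise.
  effectMask <- rep(1, nO)
  effectMask[core] <- 0
  allSpecies <- unique(md$plant_label)
  spLoad <- matrix(rnorm(length(allSpecies) * nO, 0, cfg$species_effect_sd),
                   nO, length(allSpecies), dimnames = list(otu_ids, allSpecies))
  hydLoad <- rnorm(nO, 0, cfg$hydrology_effect)
  covVars <- names(cfg$covariate_effects)
  covLoad <- matrix(rnorm(length(covVars) * nO), nO, length(covVars),
                    dimnames = list(otu_ids, covVars))
  covZ <- vapply(covVars, function(v) {
    x <- md[[v]]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, nS) else (x - mean(x)) / s
  }, numeric(nS))

  ## ---- expected compositions ------------------------------------------
  expected <- matrix(0, nO, nS, dimnames = list(otu_ids, md$sample_id))
  logFold <- log(cfg$endophyte_fold)
  plantExpect <- list()  # pre-fraction expected composition per plant/ref sample
  for (j in seq_len(nS)) {
    sys <- md$system[j]
    w <- baseW[, sys]
    lw <- ifelse(w > 0, log(w), -Inf)
    eff <- spLoad[, md$plant_label[j]]
    if (md$hydrology[j] == "submerged") eff <- eff + hydLoad
    for (k in seq_along(covVars)) {
      eff <- eff + cfg$covariate_effects[[covVars[k]]] * covZ[j, k] * covLoad[, k]
    }
    lw <- lw + effectMask * eff
    ew <- exp(lw)
    ew[w == 0] <- 0
    p <- ew / sum(ew)
    if (md$fraction[j] == "endophyte" && logFold != 0) {
      p2 <- p
      p2[endo] <- p2[endo] * cfg$endophyte_fold
      p <- p2 / sum(p2)
    }
    expected[, j] <- p
  }

  ## ---- draws: plant-level latent, library-level jitter, counts --------
  counts <- matrix(0L, nO, nS, dimnames = list(otu_ids, md$sample_id))
  libs <- sample(cfg$library_size_range[1]:cfg$library_size_range[2], nS,
                 replace = TRUE)
  # latent compositions are shared by all libraries of the same plant unit so
  # that endophyte-vs-epiphyte contrasts within a plant reflect only the
  # fraction effect plus technical noise
  units <- unique(md$plant_unit[!is.na(md$plant_unit)])
  latent <- matrix(0, nO, length(units), dimnames = list(otu_ids, units))
  for (u in units) {
    j <- which(md$plant_unit == u)[1L]
    # plant latent drawn around the pre-enrichment (epiphyte-scale) expectation
    jEpi <- which(md$plant_unit == u & md$fraction == "epiphyte")[1L]
    if (is.na(jEpi)) jEpi <- j
    latent[, u] <- .rdirichlet(cfg$dispersion * expected[, jEpi])
  }
  for (j in seq_len(nS)) {
    if (!is.na(md$plant_unit[j])) {
      p <- latent[, md$plant_unit[j]]
      if (md$fraction[j] == "endophyte" && logFold != 0) {
        p[endo] <- p[endo] * cfg$endophyte_fold
        p <- p / sum(p)
      }
      p <- .rdirichlet(cfg$replicate_concentration * p)
    } else {
      p <- .rdirichlet(cfg$dispersion * expected[, j])
    }
    counts[, j] <- as.integer(rmultinom(1L, libs[j], p))
  }
  # guard against the (practically impossible at these library sizes)
  # all-zero sample
  zz <- colSums(counts) == 0
  if (any(zz)) counts[1L, zz] <- 1L

  table <- OtuTable(counts, taxonomy = taxonomy, domain = "bacteria",
                    sampleData = md)
  truth <- list(
    core_ids = otu_ids[core],
    system_specific_ids = list(amb = otu_ids[ambSpec], sph = otu_ids[sphSpec]),
    endophyte_ids = otu_ids[endo],
    otu_ids = otu_ids,
    expected = expected,
    covariates = md[, c("sample_id", "pH", "temperature", "ch4")]
  )
  list(table = table, metadata = md, truth = truth)
}

#' Recovery metrics against planted truth
#'
#' Compares computed result sets with the planted OTU sets of a synthetic
#' study: sensitivity (recovered fraction of the planted set) and
#' false-discovery proportion (fraction of the result set outside the planted
#' set) per comparison.
#'
#' @param truth the `truth` element of a [generateStudy()] result.
#' @param core optional [CoreResult-class]; compared against planted core ids.
#' @param endophyte_calls optional result of [classifyEndophytes()];
#'   qualifying OTUs compared against planted endophyte ids.
#' @return `data.frame` with one row per comparison: `set`, `n_planted`,
#'   `n_called`, `n_recovered`, `sensitivity`, `fdp`.
#' @export
truthRecoveryReport <- function(truth, core = NULL, endophyte_calls = NULL) {
  rows <- list()
  scoreSet <- function(name, called, planted) {
    unknown <- setdiff(called, truth$otu_ids)
    if (length(unknown)) {
      stop("result ids outside the study's OTU universe: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    data.frame(
      set = name, n_planted = length(planted), n_called = length(called),
      n_recovered = length(intersect(called, planted)),
      sensitivity = if (length(planted)) length(intersect(called, planted)) / length(planted) else NA_real_,
      fdp = if (length(called)) length(setdiff(called, planted)) / length(called) else 0,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(core)) {
    rows[["core"]] <- scoreSet("core", coreIds(core), truth$core_ids)
  }
  if (!is.null(endophyte_calls)) {
    called <- endophyte_calls$calls$otu_id[endophyte_calls$calls$qualifies]
    rows[["endophyte"]] <- scoreSet("endophyte", called, truth$endophyte_ids)
  }
  if (!length(rows)) stop("nothing to score: supply 'core' and/or 'endophyte_calls'")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
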