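#' Cohort simulation profile
#'
#' Describes the marginal structure of a simulated neoadjuvant trial
#' cohort: stage and histology mix, PD-L1 TPS groups, driver-alteration
#' fraction, the surgery/resection branching, the mixture distribution of
#' percent viable tumor cells and an exponential survival model. Defaults
#' reproduce the enrolment mix of a 181-patient resectable NSCLC cohort:
#' stages IB:IIA:IIB:IIIA:IIIB = 18:16:55:70:22, 38% squamous, TPS groups
#' 69:28:49:35, EGFR/ALK alterations in 17/181, 22/181 without surgery,
#' and among resected evaluable tumors a viable-percent mixture with an
#' atom at 0 (pCR, mass 8/143) and total mass at or below 10% viable
#' (MPR-range, 29/143).
#'
#' @param nPatients number of patients to simulate.
#' @param stageWeights named weights over stages IB, IIA, IIB, IIIA, IIIB.
#' @param squamousFraction proportion with squamous histology.
#' @param tpsWeights named weights over TPS groups `<1%`, `1-49%`, `>=50%`,
#'   `unknown`.
#' @param egfrAlkFraction proportion with EGFR mutation or ALK
#'   rearrangement (excluded from the MPR-evaluable population).
#' @param noSurgeryFraction proportion not undergoing surgery.
#' @param incompleteResectionFraction proportion of operated patients with
#'   R1/R2 resection (precluding MPR by rule).
#' @param viableMixture named numeric: `pcrMass` (atom at 0), `mprMass`
#'   (total mass at viable <= 10, including the atom), `shapeA`/`shapeB`
#'   (Beta shape of the rescaled (10, 100] component).
#' @param survivalModel named numeric monthly exponential rates:
#'   `osRateMpr`, `osRateNonMpr`, `dfsRateMpr`, `dfsRateNonMpr`,
#'   `censRate`.
#' @return A `CohortProfile` object.
#' @export
#' @examples
#' cohortProfile(nPatients = 50)
cohortProfile <- function(nPatients = 181,
                          stageWeights = c(IB = 18, IIA = 16, IIB = 55,
                                           IIIA = 70, IIIB = 22) / 181,
                          squamousFraction = 69 / 181,
                          tpsWeights = c("<1%" = 69, "1-49%" = 28,
                                         ">=50%" = 49, unknown = 35) / 181,
                          egfrAlkFraction = 17 / 181,
                          noSurgeryFraction = 22 / 181,
                          incompleteResectionFraction = 6 / 143,
                          viableMixture = c(pcrMass = 8 / 143,
                                            mprMass = 29 / 143,
                                            shapeA = 1.3, shapeB = 0.9),
                          survivalModel = c(osRateMpr = 0.0025,
                                            osRateNonMpr = 0.0075,
                                            dfsRateMpr = 0.0035,
                                            dfsRateNonMpr = 0.0110,
                                            censRate = 0.0120)) {
  new("CohortProfile", nPatients = as.integer(nPatients),
      stageWeights = stageWeights, squamousFraction = squamousFraction,
      tpsWeights = tpsWeights, egfrAlkFraction = egfrAlkFraction,
      noSurgeryFraction = noSurgeryFraction,
      incompleteResectionFraction = incompleteResectionFraction,
      viableMixture = viableMixture, survivalModel = survivalModel)
}

#' @rdname cohortProfile
#' @aliases CohortProfile-class
#' @export
setClass("CohortProfile",
  representation(nPatients = "integer", stageWeights = "numeric",
                 squamousFraction = "numeric", tpsWeights = "numeric",
                 egfrAlkFraction = "numeric", noSurgeryFraction = "numeric",
                 incompleteResectionFraction = "numeric",
                 viableMixture = "numeric", survivalModel = "numeric"))

setValidity("CohortProfile", function(object) {
  out <- tryCatch({
    if (length(object@nPatients) != 1L || is.na(object@nPatients) ||
        object@nPatients < 1L)
      stop("field 'nPatients' must be a positive count", call. = FALSE)
    .checkWeights(object@stageWeights, "stageWeights")
    .checkWeights(object@tpsWeights, "tpsWeights")
    .checkProportion(object@squamousFraction, "squamousFraction")
    .checkProportion(object@egfrAlkFraction, "egfrAlkFraction")
    .checkProportion(object@noSurgeryFraction, "noSurgeryFraction")
    .checkProportion(object@incompleteResectionFraction,
                     "incompleteResectionFraction")
    vm <- object@viableMixture
    need <- c("pcrMass", "mprMass", "shapeA", "shapeB")
    if (!all(need %in% names(vm)))
      stop("field 'viableMixture' must name pcrMass, mprMass, shapeA, shapeB",
           call. = FALSE)
    .checkProportion(vm[["pcrMass"]], "viableMixture[pcrMass]")
    .checkProportion(vm[["mprMass"]], "viableMixture[mprMass]")
    if (vm[["mprMass"]] < vm[["pcrMass"]])
      stop("field 'viableMixture': mprMass must be >= pcrMass (the atom is part of the <=10 mass)",
           call. = FALSE)
    if (any(!is.finite(vm[c("shapeA", "shapeB")])) ||
        any(vm[c("shapeA", "shapeB")] <= 0))
      stop("field 'viableMixture': Beta shapes must be positive", call. = FALSE)
    sm <- object@survivalModel
    if (any(!is.finite(sm)) || any(sm < 0))
      stop("field 'survivalModel' rates must be finite and nonnegative",
           call. = FALSE)
    TRUE
  }, error = function(e) conditionMessage(e))
  out
})

#' Simulate a clinical cohort
#'
#' Draws patient-level clinical records from a [cohortProfile()]:
#' demographics and disease characteristics, the surgery/resection
#' branching, percent viable tumor cells at resection (missing if and only
#' if no resection), and exponential disease-free and overall survival
#' with independent exponential censoring, with rates depending on MPR
#' status. The MPR-evaluable subset is `surgery & !egfr_alk_positive`.
#'
#' @param profile a `CohortProfile`.
#' @param seed integer seed; identical `(profile, seed)` give byte-identical
#'   cohorts.
#' @return A data.frame with one row per patient: `patient_id`, `stage`,
#'   `histology`, `tps_group`, `egfr_alk_positive`, `surgery`, `resection`
#'   (`R0`, `R1/R2` or `none`), `viable_percent`, `dfs_time`, `dfs_event`,
#'   `os_time`, `os_event`, `has_pre`, `has_post`.
#' @export
#' @examples
#' head(generateCohort(cohortProfile(nPatients = 20), seed = 1))
generateCohort <- function(profile, seed) {
  validObject(profile)
  set.seed(deriveSeed(seed, "cohort"))
  n <- profile@nPatients
  stage <- sample(names(profile@stageWeights), n, replace = TRUE,
                  prob = profile@stageWeights)
  histology <- ifelse(stats::runif(n) < profile@squamousFraction,
                      "squamous", "non-squamous")
  tps <- sample(names(profile@tpsWeights), n, replace = TRUE,
                prob = profile@tpsWeights)
  egfrAlk <- stats::runif(n) < profile@egfrAlkFraction
  surgery <- stats::runif(n) >= profile@noSurgeryFraction
  resection <- ifelse(!surgery, "none",
                      ifelse(stats::runif(n) < profile@incompleteResectionFraction,
                             "R1/R2", "R0"))
  vm <- profile@viableMixture
  u <- stats::runif(n)
  viable <- ifelse(u < vm[["pcrMass"]], 0,
            ifelse(u < vm[["mprMass"]], stats::runif(n, 0, 10),
                   10 + 90 * stats::rbeta(n, vm[["shapeA"]], vm[["shapeB"]])))
  viable[resection == "none"] <- NA_real_
  mpr <- !is.na(viable) & viable <= 10 & resection == "R0"

  sm <- profile@survivalModel
  rexpSafe <- function(rate) {
    rate <- pmax(rate, 1e-12)  # rate 0 = effectively no events
    stats::rexp(n, rate)
  }
  dfsEventTime <- rexpSafe(ifelse(mpr, sm[["dfsRateMpr"]], sm[["dfsRateNonMpr"]]))
  osEventTime <- rexpSafe(ifelse(mpr, sm[["osRateMpr"]], sm[["osRateNonMpr"]]))
  censTime <- rexpSafe(rep(sm[["censRate"]], n))
  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    stage = stage, histology = histology, tps_group = tps,
    egfr_alk_positive = egfrAlk, surgery = surgery, resection = resection,
    viable_percent = viable,
    dfs_time = pmin(dfsEventTime, censTime),
    dfs_event = as.integer(dfsEventTime <= censTime),
    os_time = pmin(osEventTime, censTime),
    os_event = as.integer(osEventTime <= censTime),
    has_pre = TRUE, has_post = surgery,
    stringsAsFactors = FALSE)
}

#' Planted-effect specification for the immunome generator
#'
#' Names the marker-combination features causally linked to MPR in a
#' simulation, the direction and size of the link (a standardized mean
#' shift on the latent log-odds scale of the corresponding cell
#' population), an optional outcome-linked detection dropout, and an
#' optional post-treatment expansion/contraction shift applied to MPR
#' patients.
#'
#' @param features character feature ids (see [featureId()]).
#' @param direction `+1` (positively associated with MPR) or `-1` per
#'   feature; recycled.
#' @param effectSize nonnegative Cohen's-d-scale shift per feature;
#'   recycled.
#' @param detectionShift per-feature dropout asymmetry in `[-1, 1]`:
#'   positive values add Bernoulli dropout of that probability in non-MPR
#'   samples (the feature is detected more often in MPR), negative values
#'   add it in MPR samples. Default 0.
#' @param postShift per-feature post-treatment shift (d scale, sign =
#'   expansion/contraction) applied to MPR patients. Default 0.
#' @return An `EffectSpec` object. `effectSpec(character(0))` is the null
#'   specification.
#' @export
effectSpec <- function(features, direction = 1, effectSize = 1,
                       detectionShift = 0, postShift = 0) {
  k <- length(features)
  new("EffectSpec", features = as.character(features),
      direction = rep_len(as.numeric(direction), k),
      effectSize = rep_len(as.numeric(effectSize), k),
      detectionShift = rep_len(as.numeric(detectionShift), k),
      postShift = rep_len(as.numeric(postShift), k))
}

#' @rdname effectSpec
#' @aliases EffectSpec-class
#' @export
setClass("EffectSpec",
  representation(features = "character", direction = "numeric",
                 effectSize = "numeric", detectionShift = "numeric",
                 postShift = "numeric"))

setValidity("EffectSpec", function(object) {
  msg <- character()
  if (any(!is.finite(object@effectSize)) || any(object@effectSize < 0))
    msg <- c(msg, "effect sizes must be finite and nonnegative")
  if (!all(object@direction %in% c(-1, 1)))
    msg <- c(msg, "directions must be +1 or -1")
  if (any(abs(object@detectionShift) > 1))
    msg <- c(msg, "detection shifts must lie in [-1, 1]")
  if (anyDuplicated(object@features))
    msg <- c(msg, "causal feature ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Latent cell populations behind a simulated immunome
#'
#' Each tube hosts a fixed set of latent cell populations; a population
#' has one +/- profile over the tube's markers (hence maps to exactly one
#' combination signature) and a mean mixing weight. Patient immunomes are
#' Dirichlet draws around the mean weights, so the combination abundances
#' of a tube always form an exact compositional partition of 100%.
#'
#' @param panel a [PanelDefinition][PanelDefinition-class].
#' @param populationsPerTube latent populations per tube.
#' @param meanShape Gamma shape for the population mean weights; smaller
#'   values spread the weights and widen the prevalence spectrum.
#' @param seed integer seed (populations are a property of the simulated
#'   assay, fixed across cohorts drawn from them).
#' @return A list with per-tube `signs` matrices (populations x markers,
#'   values `"+"`/`"-"`), `mu` mean weight vectors, and the vector
#'   `featureIds` of distinct observed signatures.
#' @export
makePopulations <- function(panel, populationsPerTube = 80,
                            meanShape = 0.5, seed = 1) {
  validObject(panel)
  set.seed(deriveSeed(seed, "populations"))
  tubes <- lapply(names(panel@tubes), function(tb) {
    mk <- panel@tubes[[tb]]
    posProb <- stats::runif(length(mk), 0.2, 0.8)
    signs <- matrix(ifelse(stats::runif(populationsPerTube * length(mk)) <
                             rep(posProb, each = populationsPerTube),
                           "+", "-"),
                    nrow = populationsPerTube,
                    dimnames = list(NULL, mk))
    g <- stats::rgamma(populationsPerTube, shape = meanShape)
    mu <- g / sum(g)
    ids <- featureId(tb, lapply(seq_len(populationsPerTube),
                                function(i) signs[i, ]), panel)
    list(tube = tb, signs = signs, mu = mu, ids = ids)
  })
  names(tubes) <- names(panel@tubes)
  list(tubes = tubes,
       featureIds = unique(unlist(lapply(tubes, `[[`, "ids"),
                                  use.names = FALSE)))
}

# expected detection probability of each population's feature given the
# Beta marginal of its Dirichlet weight and the limit of detection
.populationDetection <- function(pop, concentration, lod) {
  lapply(pop$tubes, function(tb) {
    stats::pbeta(lod / 100, concentration * tb$mu,
                 concentration * (1 - tb$mu), lower.tail = FALSE)
  })
}

#' Choose realizable causal features for a planted-effect simulation
#'
#' Picks populations whose signature is unique within their tube, not
#' excluded by the panel's impossibility rules, and whose expected
#' detection probability falls in a target band (by default below the 85%
#' prevalence threshold but comfortably above the 50% detection filter,
#' so planted features travel the non-prevalent pipeline branch).
#'
#' @param populations result of [makePopulations()].
#' @param panel the [PanelDefinition][PanelDefinition-class].
#' @param n number of features to pick.
#' @param detectionBand length-2 numeric band of expected detection
#'   probabilities.
#' @param concentration,lod generator parameters (must match the values
#'   later given to [generateImmunome()]).
#' @return Character feature ids, spread across tubes.
#' @export
pickCausalFeatures <- function(populations, panel, n,
                               detectionBand = c(0.65, 0.84),
                               concentration = 50, lod = 0.1) {
  det <- .populationDetection(populations, concentration, lod)
  cand <- unlist(lapply(populations$tubes, function(tb) {
    d <- det[[tb$tube]]
    dup <- duplicated(tb$ids) | duplicated(tb$ids, fromLast = TRUE)
    ok <- !dup & d >= detectionBand[1] & d <= detectionBand[2]
    parsed <- parseFeatureId(tb$ids[ok], panel)
    ok2 <- !.matchesExclusion(parsed, panel, quiet = TRUE)
    tb$ids[ok][ok2]
  }), use.names = FALSE)
  if (length(cand) < n)
    stop(sprintf("only %d populations fall in the detection band; asked for %d",
                 length(cand), n))
  # spread across tubes: round-robin over the per-tube candidate lists
  cand[round(seq(1L, length(cand), length.out = n))]
}

#' Simulate pre- and post-treatment immunome matrices
#'
#' Generates patient abundance matrices from the latent cell-population
#' mixture: per patient and tube, population weights are Dirichlet draws
#' around the population means; planted effects shift the log-odds of the
#' causal population's weight by `direction * d * sigma` (where `sigma` is
#' the latent log-odds standard deviation) in MPR patients, followed by
#' renormalization, so compositional closure is exact. Multiplicative
#' log-normal noise emulates measurement error. Abundances below the limit
#' of detection, and an optional Bernoulli dropout mask, are zeroed
#' without renormalization (assay dropout breaks closure, as it does in
#' real gated data). Post-treatment matrices share the patient's latent
#' weights, with `postShift` expansion/contraction applied to MPR
#' patients.
#'
#' @param cohort data.frame from [generateCohort()].
#' @param panel a [PanelDefinition][PanelDefinition-class].
#' @param effects an [effectSpec()]; use `effectSpec(character(0))` for a
#'   null cohort.
#' @param seed integer seed.
#' @param populations optional result of [makePopulations()]; generated
#'   from `(panel, seed)` when omitted.
#' @param populationsPerTube,meanShape passed to [makePopulations()] when
#'   `populations` is omitted.
#' @param concentration Dirichlet concentration of patient weights around
#'   the population means.
#' @param noiseSd log-normal measurement noise (sd of log abundance).
#' @param lod limit of detection, percent; abundances below it read 0.
#' @param dropoutRate baseline Bernoulli dropout probability applied to
#'   every feature value independently of abundance.
#' @param applyMask set `FALSE` to skip the limit-of-detection/dropout
#'   zeroing (exposes the exact compositional partition).
#' @return A list with `pre` and `post`
#'   [ImmunomeExperiment][ImmunomeExperiment-class] objects (`post`
#'   columns restricted to patients with a post-treatment sample) and the
#'   `populations` used.
#' @export
generateImmunome <- function(cohort, panel, effects = effectSpec(character(0)),
                             seed = 1, populations = NULL,
                             populationsPerTube = 80, meanShape = 0.5,
                             concentration = 50, noiseSd = 0.15, lod = 0.1,
                             dropoutRate = 0.02, applyMask = TRUE) {
  validObject(panel)
  validObject(effects)
  if (!all(c("patient_id", "viable_percent", "resection") %in% names(cohort)))
    stop("cohort lacks required columns; was it made by generateCohort()?")
  if (is.null(populations))
    populations <- makePopulations(panel, populationsPerTube, meanShape, seed)

  # resolve planted effects onto populations
  effIdx <- vector("list", length(populations$tubes))
  names(effIdx) <- names(populations$tubes)
  if (length(effects@features)) {
    parsed <- parseFeatureId(effects@features, panel)
    excluded <- .matchesExclusion(parsed, panel, quiet = TRUE)
    if (any(excluded))
      stop(sprintf("effect planted on excluded (impossible) combination(s): %s",
                   paste(effects@features[excluded], collapse = ", ")))
    for (k in seq_along(effects@features)) {
      tb <- parsed[[k]]$tube
      hit <- which(populations$tubes[[tb]]$ids == effects@features[k])
      if (!length(hit))
        stop(sprintf("causal feature '%s' matches no latent population",
                     effects@features[k]))
      effIdx[[tb]] <- rbind(effIdx[[tb]],
                            cbind(pop = hit, spec = rep(k, length(hit))))
    }
  }

  mpr <- !is.na(cohort$viable_percent) & cohort$viable_percent <= 10 &
    cohort$resection == "R0"
  n <- nrow(cohort)

  set.seed(deriveSeed(seed, "immunome"))
  featIds <- populations$featureIds
  draw <- function(postShifted) {
    out <- matrix(0, nrow = length(featIds), ncol = n,
                  dimnames = list(featIds, cohort$patient_id))
    for (tb in names(populations$tubes)) {
      pt <- populations$tubes[[tb]]
      P <- length(pt$mu)
      alpha <- concentration * pt$mu
      # patient latent weights: Dirichlet via normalized Gamma draws
      g <- matrix(stats::rgamma(n * P, shape = rep(alpha, each = n)),
                  nrow = n)
      w <- g / rowSums(g)
      ei <- effIdx[[tb]]
      if (!is.null(ei)) {
        sigma <- sqrt(trigamma(alpha[ei[, "pop"]]) +
                      trigamma(concentration - alpha[ei[, "pop"]]))
        for (r in seq_len(nrow(ei))) {
          k <- ei[r, "spec"]; j <- ei[r, "pop"]
          delta <- effects@direction[k] * effects@effectSize[k] * sigma[r]
          if (postShifted)
            delta <- delta + effects@postShift[k] * sigma[r]
          l <- stats::qlogis(pmin(pmax(w[mpr, j], 1e-12), 1 - 1e-12))
          w[mpr, j] <- stats::plogis(l + delta)
        }
        w <- w / rowSums(w)
      }
      if (noiseSd > 0) {
        w <- w * exp(matrix(stats::rnorm(n * P, sd = noiseSd), nrow = n))
        w <- w / rowSums(w)
      }
      ab <- 100 * rowsum(t(w), group = pt$ids)  # distinct signature x patient
      out[rownames(ab), ] <- ab
    }
    out
  }

  mask <- function(mat) {
    if (!applyMask) return(mat)
    mat[mat < lod] <- 0
    if (dropoutRate > 0)
      mat[matrix(stats::runif(length(mat)) < dropoutRate, nrow = nrow(mat))] <- 0
    if (length(effects@features)) {
      for (k in seq_along(effects@features)) {
        ds <- effects@detectionShift[k]
        if (ds == 0) next
        f <- effects@features[k]
        grp <- if (ds > 0) !mpr else mpr
        drop <- stats::runif(n) < abs(ds) & grp
        mat[f, drop] <- 0
      }
    }
    mat
  }

  asExperiment <- function(mat, timepoint, keep = rep(TRUE, n)) {
    parsed <- parseFeatureId(rownames(mat), panel)
    rd <- DataFrame(tube = vapply(parsed, `[[`, "", "tube"),
                    signature = vapply(parsed, function(p)
                      paste0(names(p$signs), p$signs, collapse = ""), ""),
                    row.names = rownames(mat))
    cd <- DataFrame(patient_id = cohort$patient_id[keep],
                    timepoint = timepoint,
                    row.names = paste0(cohort$patient_id[keep], "_", timepoint))
    m <- mat[, keep, drop = FALSE]
    colnames(m) <- rownames(cd)
    se <- SummarizedExperiment(assays = list(abundance = m),
                               rowData = rd, colData = cd)
    new("ImmunomeExperiment", se)
  }

  pre <- mask(draw(postShifted = FALSE))
  post <- mask(draw(postShifted = TRUE))
  hasPost <- if ("has_post" %in% names(cohort)) cohort$has_post else rep(TRUE, n)
  list(pre = asExperiment(pre, "pre"),
       post = asExperiment(post, "post", keep = hasPost),
       populations = populations)
}

#' Simulate per-patient variant counts and coverage footprints
#'
#' Each patient receives a Poisson count of protein-affecting mutations
#' with mean `rate * footprintMb`, a non-protein-affecting count, and a
#' coding footprint (bases at >= 7x unique coverage). Rates are either
#' supplied directly or drawn from a three-component mixture positioned so
#' the TMB groups `<10`, `10-15` and `>=16` mutations/Mb arise in the
#' expected proportions 60:10:15.
#'
#' @param cohort data.frame from [generateCohort()].
#' @param seed integer seed.
#' @param rates optional per-patient (or scalar) true mutation rates per
#'   megabase; overrides the mixture.
#' @param footprintMb mean coding footprint in megabases.
#' @param groupProbs mixture weights of the low/mid/high rate components.
#' @param rateRanges list of length-2 numeric ranges for the uniform
#'   low/mid/high rate components.
#' @return data.frame with `patient_id`, `protein_affecting`,
#'   `non_protein_affecting`, `covered_bases`, `true_rate`.
#' @export
generateMutationData <- function(cohort, seed, rates = NULL,
                                 footprintMb = 30,
                                 groupProbs = c(60, 10, 15) / 85,
                                 rateRanges = list(low = c(1, 9),
                                                   mid = c(11.5, 14.5),
                                                   high = c(17, 40))) {
  if (nrow(cohort) == 0L) stop("cohort is empty")
  set.seed(deriveSeed(seed, "mutations"))
  n <- nrow(cohort)
  if (is.null(rates)) {
    comp <- sample(3L, n, replace = TRUE, prob = groupProbs)
    rr <- rateRanges[c("low", "mid", "high")]
    rates <- stats::runif(n, vapply(rr, `[`, 0, 1)[comp],
                          vapply(rr, `[`, 0, 2)[comp])
  } else {
    rates <- rep_len(rates, n)
    if (any(!is.finite(rates)) || any(rates < 0))
      stop("rates must be finite and nonnegative")
  }
  fp <- stats::runif(n, 0.9 * footprintMb, 1.1 * footprintMb)
  protein <- stats::rpois(n, rates * fp)
  nonProtein <- stats::rpois(n, 1.5 * rates * fp)
  data.frame(patient_id = cohort$patient_id,
             protein_affecting = protein,
             non_protein_affecting = nonProtein,
             covered_bases = as.integer(round(fp * 1e6)),
             true_rate = rates,
             stringsAsFactors = FALSE)
}
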