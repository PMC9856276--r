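# Cohort demographic marginals emulated by the generator (means/SDs/ranges
# and case-control compositions of the three-cohort study design).
.COHORT_PARAMS <- list(
  serum     = list(cohort = "OPDC",  maleFrac = 0.570,
                   ageCase = c(68.6, 9.6, 32.2, 90.9),
                   ageCtrl = c(62.4, 10.9, 28.5, 88.9)),
  csf       = list(cohort = "OPDC",  maleFrac = 0.624,
                   ageCase = c(65.8, 8.8, 39.7, 83.6),
                   ageCtrl = c(66.1, 7.9, 55.3, 85.1)),
  brain     = list(cohort = "PUKBB", maleFrac = 0.784,
                   ageCase = c(79.2, 6.0, 63, 90),
                   ageCtrl = c(78.2, 11.4, 58, 91)),
  serum_rep = list(cohort = "TP",    maleFrac = 0.608,
                   ageCase = c(66.9, 8.8, 37, 85.6),
                   ageCtrl = c(62.1, 9.7, 36.9, 87.4))
)

#' Configure the synthetic proteomic study
#'
#' Defaults emulate the published three-cohort design: a serum training set
#' (n = 572, 69.9\% cases), a CSF set (n = 85, 82.4\% cases), a post-mortem
#' brain set (n = 37, 64.9\% cases) and a serum replication set (n = 932,
#' 81.9\% cases); two assay-panel generations of 1129 and 4006 proteins
#' sharing 1047 assays; 30 planted case-associated proteins; 10
#' severity-correlated proteins; two correlated co-expression blocks.
#'
#' @param nSamples named integer vector of per-modality sample sizes.
#' @param caseFraction named numeric vector of per-modality case fractions
#'   (case counts are fixed at \code{round(n * fraction)}, not sampled).
#' @param nProteins named sizes of the two panel versions.
#' @param nOverlap number of assays shared by the two versions.
#' @param nInformative,informativeEffect count and common log2 effect of
#'   planted case-associated proteins (ignored when \code{informative} given).
#' @param informative data.frame(id, effect) of planted status effects on the
#'   log2 scale; ids must belong to a panel.
#' @param severityProteins data.frame(id, slope) of proteins whose log2 level
#'   tracks the latent per-case severity.
#' @param moduleBlocks list of \code{list(size=, rho=)} co-expression blocks
#'   (members are allocated automatically from the shared panel) or
#'   \code{list(members=, rho=)} with explicit ids.
#' @param batchSpec data.frame(label, shift, scale, fraction) of batch
#'   structure applied on the log2 scale at generation.
#' @param noiseSd residual log2 measurement noise SD.
#' @param attenuation named per-modality multiplier on planted effects
#'   (1 = full effect, 0 = pure noise in that tissue).
#' @param effectSeverityCoupling slope coupling planted status effects to the
#'   latent severity: a case's effect is scaled by
#'   \code{max(0, 1 + coupling * severity)}. 0 (default) gives
#'   severity-independent effects.
#' @param versions named per-modality panel version ("v2" or "v3").
#' @param seed integer master seed; identical configs generate identical data.
#' @return a validated \linkS4class{SynthConfig}.
#' @export
synthConfig <- function(
    nSamples = c(serum = 572, csf = 85, brain = 37, serum_rep = 932),
    caseFraction = c(serum = 0.699, csf = 0.824, brain = 0.649,
                     serum_rep = 0.819),
    nProteins = c(v2 = 1129, v3 = 4006),
    nOverlap = 1047,
    nInformative = 30, informativeEffect = 0.6,
    informative = NULL,
    severityProteins = NULL,
    moduleBlocks = list(list(size = 40, rho = 0.7),
                        list(size = 40, rho = 0.7)),
    batchSpec = data.frame(label = "B1", shift = 0, scale = 1, fraction = 1),
    noiseSd = 0.5,
    attenuation = NULL,
    effectSeverityCoupling = 0,
    versions = c(serum = "v2", csf = "v3", brain = "v2", serum_rep = "v3"),
    seed = 1) {
  if (is.null(names(nSamples))) stop("nSamples must be named by modality")
  caseFraction <- caseFraction[names(nSamples)]
  if (anyNA(caseFraction)) stop("caseFraction must cover every modality")
  if (is.null(attenuation))
    attenuation <- stats::setNames(rep(1, length(nSamples)), names(nSamples))
  if (is.null(informative)) {
    informative <- data.frame(
      id = sprintf("P%04d", seq_len(nInformative)),
      effect = rep(informativeEffect, nInformative),
      stringsAsFactors = FALSE)
  }
  nInf <- nrow(informative)
  if (is.null(severityProteins)) {
    severityProteins <- data.frame(
      id = sprintf("P%04d", nInf + seq_len(min(10L, max(0L, nOverlap - nInf)))),
      slope = 0.3, stringsAsFactors = FALSE)
  }
  # allocate block members from shared-panel ids not already carrying signal
  reserved <- c(informative$id, severityProteins$id)
  free <- setdiff(sprintf("P%04d", seq_len(nOverlap)), reserved)
  blocks <- list()
  for (b in moduleBlocks) {
    if (!is.null(b$members)) {
      blocks[[length(blocks) + 1L]] <- list(members = b$members, rho = b$rho)
    } else {
      if (b$size > length(free)) stop("not enough free proteins for module blocks")
      blocks[[length(blocks) + 1L]] <- list(members = free[seq_len(b$size)],
                                            rho = b$rho)
      free <- free[-seq_len(b$size)]
    }
  }
  cfg <- new("SynthConfig",
    nSamples = nSamples, caseFraction = caseFraction,
    nProteins = nProteins, nOverlap = nOverlap,
    informative = informative, severityProteins = severityProteins,
    moduleBlocks = blocks, batchSpec = batchSpec, noiseSd = noiseSd,
    attenuation = attenuation,
    effectSeverityCoupling = effectSeverityCoupling,
    versions = versions, seed = seed)
  allIds <- unique(unlist(panelProteins(cfg)))
  bad <- setdiff(c(informative$id, severityProteins$id,
                   unlist(lapply(blocks, `[[`, "members"))), allIds)
  if (length(bad))
    stop("effect assigned to unknown protein id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  cfg
}

#' Protein id sets of the two panel versions
#'
#' The shared assays are ids \code{P0001..P<nOverlap>}; version-2-only assays
#' continue the P series, version-3-only assays use a Q prefix.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return named list of character vectors, one per version.
#' @export
panelProteins <- function(config) {
  ov <- sprintf("P%04d", seq_len(config@nOverlap))
  v2extra <- config@nProteins["v2"] - config@nOverlap
  v3extra <- config@nProteins["v3"] - config@nOverlap
  list(
    v2 = c(ov, if (v2extra > 0) sprintf("P%04d", config@nOverlap + seq_len(v2extra))),
    v3 = c(ov, if (v3extra > 0) sprintf("Q%04d", seq_len(v3extra))))
}

# deterministic per-protein log2 baselines shared across modalities
.proteinBaselines <- function(config) {
  panels <- panelProteins(config)
  ids <- unique(unlist(panels))
  set.seed(config@seed %% .Machine$integer.max)
  stats::setNames(stats::rnorm(length(ids), mean = 10, sd = 1.5), ids)
}

.truncNorm <- function(n, mean, sd, lo, hi)
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))

#' Generate one synthetic cohort
#'
#' Draws a raw-RFU-scale matrix \code{2^(baseline + status effect +
#' severity slope + block factors + batch shift + noise)} with metadata
#' carrying status, age, sex, cohort, MoCA, MDS-UPDRS III, LEDD and batch.
#' Identical config and modality always yield identical output. The latent
#' per-case severity and the planted truth are recorded in
#' \code{metadata()} of the result for oracle checks.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param modality one of the modalities named in \code{config}.
#' @return a raw \linkS4class{ProteinExperiment} with \code{colData} filled.
#' @export
generateCohort <- function(config, modality = names(config@nSamples)[1L]) {
  methods::validObject(config)
  if (!modality %in% names(config@nSamples))
    stop("unknown modality: ", modality)
  baselines <- .proteinBaselines(config)   # consumes the master seed stream
  panel <- panelProteins(config)[[config@versions[[modality]]]]
  n <- as.integer(config@nSamples[[modality]])
  nCase <- as.integer(round(n * config@caseFraction[[modality]]))
  cp <- .COHORT_PARAMS[[modality]]
  if (is.null(cp)) cp <- .COHORT_PARAMS[["serum"]]

  off <- match(modality, names(config@nSamples))
  set.seed((config@seed + 9973L * off) %% .Machine$integer.max)

  status <- factor(c(rep("case", nCase), rep("control", n - nCase)),
                   levels = .STATUS_LEVELS)
  sid <- sprintf("%s_S%04d", modality, seq_len(n))
  age <- numeric(n)
  age[status == "case"] <- .truncNorm(nCase, cp$ageCase[1], cp$ageCase[2],
                                      cp$ageCase[3], cp$ageCase[4])
  age[status == "control"] <- .truncNorm(n - nCase, cp$ageCtrl[1],
                                         cp$ageCtrl[2], cp$ageCtrl[3],
                                         cp$ageCtrl[4])
  sex <- factor(ifelse(stats::runif(n) < cp$maleFrac, "male", "female"),
                levels = c("female", "male"))
  sev <- rep(NA_real_, n)
  sev[status == "case"] <- stats::rnorm(nCase)
  moca <- updrs3 <- rep(NA_real_, n)
  if (modality != "brain") {   # clinical scales unavailable for brain donors
    moca[status == "case"] <- round(pmin(30, pmax(0,
      24.2 - 2.5 * sev[status == "case"] + stats::rnorm(nCase, 0, 1.5))))
    moca[status == "control"] <- round(.truncNorm(n - nCase, 26.8, 2.7, 0, 30))
    updrs3[status == "case"] <- round(pmax(0, 27 + 9 * sev[status == "case"] +
                                              stats::rnorm(nCase, 0, 3)))
    updrs3[status == "control"] <- round(pmin(19, abs(stats::rnorm(n - nCase, 0, 2.9))))
  }
  ledd <- rep(0, n)   # disease-free controls take no dopaminergic medication
  ledd[status == "case"] <- round(.truncNorm(nCase, 353, 264, 0, 1450))
  bs <- config@batchSpec
  counts <- diff(round(cumsum(c(0, bs$fraction)) * n))
  batch <- sample(rep(as.character(bs$label), counts))
  dates <- as.Date("2017-01-01") + sample.int(730L, n, replace = TRUE)
  prep <- dates - sample.int(30L, n, replace = TRUE)

  p <- length(panel)
  X <- matrix(stats::rnorm(n * p, 0, config@noiseSd), n, p,
              dimnames = list(sid, panel))
  X <- sweep(X, 2L, baselines[panel], `+`)
  att <- config@attenuation[[modality]]
  cpl <- config@effectSeverityCoupling
  isCase <- status == "case"
  mult <- ifelse(isCase, pmax(0, 1 + cpl * ifelse(is.na(sev), 0, sev)), 0)
  inf <- config@informative[config@informative$id %in% panel, , drop = FALSE]
  if (nrow(inf))
    X[, inf$id] <- X[, inf$id] + outer(mult, inf$effect * att)
  sp <- config@severityProteins[config@severityProteins$id %in% panel, , drop = FALSE]
  if (nrow(sp)) {
    sv <- ifelse(is.na(sev), 0, sev)
    X[, sp$id] <- X[, sp$id] + outer(sv, sp$slope * att)
  }
  for (b in config@moduleBlocks) {
    mem <- intersect(b$members, panel)
    if (!length(mem)) next
    lambda <- config@noiseSd * sqrt(b$rho / (1 - b$rho))
    f <- stats::rnorm(n)
    X[, mem] <- X[, mem] + lambda * f
  }
  # batch location/scale on the log2 scale, about each protein's baseline
  for (i in seq_len(nrow(bs))) {
    rowsB <- batch == bs$label[i]
    if (!any(rowsB) || (bs$shift[i] == 0 && bs$scale[i] == 1)) next
    ctr <- sweep(X[rowsB, , drop = FALSE], 2L, baselines[panel], `-`)
    X[rowsB, ] <- sweep(ctr * bs$scale[i], 2L, baselines[panel], `+`) + bs$shift[i]
  }

  md <- data.frame(sample_id = sid, status = status, age = age, sex = sex,
                   cohort = cp$cohort, modality = modality, moca = moca,
                   updrs3 = updrs3, ledd = ledd, batch = batch,
                   assay_date = dates, prep_date = prep,
                   stringsAsFactors = FALSE)
  pe <- ProteinExperiment(2^X, sampleData = md, transformState = "raw")
  S4Vectors::metadata(pe)$latentSeverity <- stats::setNames(sev, sid)
  S4Vectors::metadata(pe)$planted <- list(
    informative = inf, severityProteins = sp,
    blocks = config@moduleBlocks, attenuation = att)
  pe
}

#' Generate the full multi-modality study
#'
#' The same planted proteins carry attenuation-scaled effects in every
#' modality; panel membership follows each modality's assay version with the
#' configured cross-version overlap.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param modalities modalities to generate (default all configured).
#' @return named list of \linkS4class{ProteinExperiment}s.
#' @export
generateMultimodalStudy <- function(config,
                                    modalities = names(config@nSamples)) {
  stats::setNames(lapply(modalities, function(m) generateCohort(config, m)),
                  modalities)
}

#' Inject batch location/scale effects into an expression matrix
#'
#' Per-batch location shifts and scale factors are applied on the log2 scale
#' (about each protein's grand mean) and mapped back to the matrix's
#' transform state, so a raw matrix stays raw.
#'
#' @param pe a \linkS4class{ProteinExperiment} whose \code{colData} has a
#'   \code{batch} column covering all samples.
#' @param batchSpec data.frame(label, shift, scale).
#' @return the perturbed ProteinExperiment.
#' @export
injectBatchEffects <- function(pe, batchSpec) {
  md <- sampleData(pe)
  if (!"batch" %in% colnames(md)) stop("metadata has no batch column")
  unknown <- setdiff(unique(md$batch), as.character(batchSpec$label))
  if (length(unknown))
    stop("unknown batch label(s): ", paste(unknown, collapse = ", "))
  raw <- transformState(pe) == "raw"
  X <- proteinValues(pe)
  if (raw) X <- log2(X)
  mu <- colMeans(X)
  for (i in seq_len(nrow(batchSpec))) {
    rows <- md$batch == batchSpec$label[i]
    if (!any(rows)) next
    ctr <- sweep(X[rows, , drop = FALSE], 2L, mu, `-`)
    X[rows, ] <- sweep(ctr * batchSpec$scale[i], 2L, mu, `+`) +
      batchSpec$shift[i]
  }
  if (raw) X <- 2^X
  .setValues(pe, X, transformState(pe))
}

#' Latent per-case severity recorded by the generator
#' @param pe a generated \linkS4class{ProteinExperiment}.
#' @return named numeric (NA for controls).
#' @export
latentSeverity <- function(pe) S4Vectors::metadata(pe)$latentSeverity

#' Planted-truth record of a generated cohort
#' @param pe a generated \linkS4class{ProteinExperiment}.
#' @return list with informative, severityProteins, blocks, attenuation.
#' @export
plantedTruth <- function(pe) S4Vectors::metadata(pe)$planted
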