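#' Default pipeline configuration
#'
#' The tunable parameters of the feature pipeline with their defaults:
#' 100 sections, a 10-degree diameter sweep, moving-average smoothing
#' (window 5, 2 iterations) for the internal curvature line, and a risk
#' threshold of 0.25 mm/month (the 3 mm/year guideline rate). Entries in
#' `...` override defaults; unknown keys are an error.
#'
#' @param ... named overrides of the defaults.
#' @return Named list of parameters.
#' @examples
#' pipelineConfig(n_sections = 20)$n_sections
#' @export
pipelineConfig <- function(...) {
  cfg <- list(n_sections = 100, alpha_deg = 10,
              smooth_window = 5, smooth_iterations = 2,
              class_threshold = 0.25,
              models = c("dt", "ld", "lr", "nb", "svm", "knn"),
              seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Compute the four shape features of an ascending-aorta domain
#'
#' Runs the geometric pipeline on an isolated domain (or on a full mesh
#' plus landmarks): perpendicular sections and the rotating-sweep maximum
#' diameter D, the diameter-centerline ratio DCR, the external/internal
#' curvature-line ratio EILR, and the tortuosity T.
#'
#' @param domain an [AAoDomain-class]; alternatively pass `mesh` (and
#'   optionally `centerline`, `annulusArc`, `ostiumPoint`/`ostiumArc`) to
#'   build one.
#' @param mesh,centerline,annulusArc,ostiumPoint,ostiumArc used when
#'   `domain` is missing; defaults treat the whole tube as the domain.
#' @param id patient/exam identifier stored in the output row.
#' @param config a [pipelineConfig()] list.
#' @return One-row data.frame: `patient_id, D, DCR, EILR, T, LC, kstar`
#'   (`LC` = centerline length in mm, `kstar` = section index achieving D).
#' @examples
#' tube <- makeTube("torus", R = 40, r = 12, theta = pi,
#'                  nAxial = 60, nCirc = 24)
#' cl <- extractCenterline(tube$mesh)
#' dom <- isolateAscending(tube$mesh, cl, ostiumArc = centerlineLength(cl))
#' computeShapeFeatures(dom, id = "demo", config = pipelineConfig(n_sections = 30))
#' @export
computeShapeFeatures <- function(domain = NULL, mesh = NULL,
                                 centerline = NULL, annulusArc = 0,
                                 ostiumPoint = NULL, ostiumArc = NULL,
                                 id = "exam", config = pipelineConfig()) {
  if (is.null(domain)) {
    if (is.null(mesh)) stop("supply a domain or a mesh")
    if (is.null(centerline)) centerline <- extractCenterline(mesh)
    if (is.null(ostiumPoint) && is.null(ostiumArc))
      ostiumArc <- centerlineLength(centerline)
    domain <- isolateAscending(mesh, centerline, annulusArc = annulusArc,
                               ostiumPoint = ostiumPoint,
                               ostiumArc = ostiumArc)
  }
  cl <- domain@centerline
  sections <- extractSections(domain, n = config$n_sections,
                              alphaDeg = config$alpha_deg)
  md <- maxDiameter(sections)
  geo <- shortestGeodesic(domain)
  icl <- smoothPath(domain, geo, window = config$smooth_window,
                    iterations = config$smooth_iterations)
  ecl <- externalLine(domain, sections, icl)
  data.frame(patient_id = id,
             D = md$D,
             DCR = dcr(md$D, centerlineLength(cl)),
             EILR = eilr(ecl, icl),
             T = tortuosity(cl),
             LC = centerlineLength(cl),
             kstar = md$k,
             stringsAsFactors = FALSE)
}

#' Growth-risk analysis of a feature cohort
#'
#' Given a table of first-exam features plus second-exam diameters and
#' inter-exam intervals, computes the growth rate and risk class per
#' patient, Spearman correlations of every feature with GR, the
#' Mann-Whitney comparison of gated versus non-gated growth rates, and
#' leave-one-out classification reports for every model in
#' `config$models`, once with the diameter alone and once with all four
#' shape features.
#'
#' @param table data.frame with columns `patient_id, D, DCR, EILR, T,
#'   D2, dt_months, gated` (see [readGrowthTable()]).
#' @param config a [pipelineConfig()] list.
#' @param paperMode passed to [loocvClassify()].
#' @return List with elements `growth` (per-patient GR and class),
#'   `correlations`, `mannWhitneyGated`, `reports` (named list of
#'   [ClassifierReport-class], names like `"svm.all"`/`"knn.D"`), and
#'   `prevalence`.
#' @examples
#' coh <- simulateCohort(n = 30, nFast = 8, seed = 3)
#' res <- classifyCohort(coh, config = pipelineConfig(models = "ld"))
#' res$reports$ld.all
#' @export
classifyCohort <- function(table, config = pipelineConfig(),
                           paperMode = FALSE) {
  .checkSchema(table, c("patient_id", "D", "DCR", "EILR", "T",
                        "D2", "dt_months", "gated"))
  if (any(table$dt_months < 6))
    stop("inter-exam interval below the 6-month inclusion minimum in row(s): ",
         paste(which(table$dt_months < 6), collapse = ", "))
  gr <- growthRate(table$D, table$D2, table$dt_months)
  cls <- assignClass(gr, threshold = config$class_threshold)
  if (nlevels(droplevels(cls)) < 2L)
    stop("cohort contains a single class (all growth rates on one side of ",
         config$class_threshold, " mm/month)")
  growth <- data.frame(patient_id = table$patient_id, GR = gr,
                       risk_class = cls, gated = as.logical(table$gated),
                       stringsAsFactors = FALSE)
  featNames <- c("D", "DCR", "EILR", "T")
  correlations <- lapply(featNames, function(f)
    spearmanCorrelation(table[[f]], gr))
  names(correlations) <- featNames
  gated <- as.logical(table$gated)
  mw <- if (any(gated) && any(!gated))
    mannWhitney(gr[gated], gr[!gated]) else NULL
  featureSets <- list(D = "D", all = featNames)
  reports <- list()
  for (m in config$models) {
    for (fsName in names(featureSets)) {
      reports[[paste(m, fsName, sep = ".")]] <-
        loocvClassify(table, cls, model = m,
                      featureSubset = featureSets[[fsName]],
                      seed = config$seed, paperMode = paperMode)
    }
  }
  list(growth = growth, correlations = correlations,
       mannWhitneyGated = mw, reports = reports,
       prevalence = mean(cls == "fast"))
}

#' Serialize a cohort analysis to JSON
#'
#' Deterministic (byte-identical for identical input) JSON rendering of a
#' [classifyCohort()] result, with a provenance block (package version,
#' seed, configuration, input digest).
#'
#' @param result list from [classifyCohort()].
#' @param config the [pipelineConfig()] used.
#' @param path optional output file; when NULL the JSON string is
#'   returned.
#' @param inputDigest optional md5 string of the input table file.
#' @return JSON string (invisibly when written to `path`).
#' @export
reportJSON <- function(result, config = pipelineConfig(), path = NULL,
                       inputDigest = NA_character_) {
  repList <- lapply(result$reports, function(r) {
    cm <- confusionCounts(r@confusion)
    list(model = r@model, features = r@features,
         confusion = as.list(cm),
         accuracy = r@accuracy, sensitivity = r@sensitivity,
         specificity = r@specificity,
         lhr_pos = .jsonNum(r@lhrPos), lhr_neg = .jsonNum(r@lhrNeg),
         auroc = r@auroc, prevalence = r@prevalence,
         scores = r@scores)
  })
  obj <- list(
    provenance = list(package = "aortamorph",
                      version = as.character(utils::packageVersion("aortamorph")),
                      seed = config$seed,
                      config = config[c("n_sections", "alpha_deg",
                                        "smooth_window", "smooth_iterations",
                                        "class_threshold")],
                      input_md5 = inputDigest),
    growth = result$growth,
    correlations = lapply(result$correlations, function(s)
      list(r = s$statistic, p = s$p.value)),
    mann_whitney_gated = if (is.null(result$mannWhitneyGated)) NULL else
      list(U = result$mannWhitneyGated$statistic,
           p = result$mannWhitneyGated$p.value),
    prevalence = result$prevalence,
    reports = repList)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          null = "null", na = "string", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

.jsonNum <- function(x) {
  if (is.na(x)) return("undefined")
  if (is.infinite(x)) return("+Inf")
  x
}
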