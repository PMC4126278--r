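#' @include reliability.R io.R
NULL

# Long CDI table (knee_id, timepoint, region, cdi, cdi_height_adjusted)
# -> wide per knee/region with baseline, followup, change columns.
.cdiWide <- function(cdi) {
  val <- ifelse(is.na(cdi$cdi_height_adjusted), cdi$cdi,
                cdi$cdi_height_adjusted)
  base <- cdi$timepoint == "baseline"
  out <- merge(
    data.frame(knee_id = cdi$knee_id[base], region = cdi$region[base],
               baseline = val[base]),
    data.frame(knee_id = cdi$knee_id[!base], region = cdi$region[!base],
               followup = val[!base]),
    by = c("knee_id", "region"), all.x = TRUE)
  out$change <- out$followup - out$baseline
  out
}

#' Construct-validity and responsiveness report for a CDI table
#'
#' Reproduces the standard validation analyses for a cohort: baseline CDI
#' and 24-month change stratified by JSN and KL grade with linear-trend
#' p-values; SRM and between-group t-tests for progressors vs
#' non-progressors; Spearman correlations of CDI with alignment and
#' joint-space width; and percent reduction of the tibiofemoral baseline
#' mean per JSN stratum relative to grade 0.
#'
#' @param cdi long CDI table as written by \code{\link{writeResults}}
#'   (columns knee_id, timepoint, region, cdi, cdi_height_adjusted;
#'   height-adjusted values are used when present)
#' @param covariates covariate table as produced by
#'   \code{\link{generateCohort}} (kneeId, jsnBaseline, klBaseline,
#'   jsnProgressor, klProgressor, and optionally hkaDeg, jswBaselineMm,
#'   jswChangeMm)
#' @return list of data.frames: \code{baselineByJSN}, \code{changeByJSN},
#'   \code{baselineByKL}, \code{changeByKL}, \code{srmByProgression},
#'   \code{correlations}, \code{percentReductionJSN}
#' @export
validationReport <- function(cdi, covariates) {
  .assert(all(c("knee_id", "timepoint", "region", "cdi") %in% names(cdi)),
          "cdi must be a long CDI table (see writeResults)")
  .assert("kneeId" %in% names(covariates),
          "covariates must have a kneeId column")
  if (!"cdi_height_adjusted" %in% names(cdi))
    cdi$cdi_height_adjusted <- NA_real_
  wide <- .cdiWide(cdi)
  wide <- merge(wide, covariates, by.x = "knee_id", by.y = "kneeId")
  regions <- c("femur", "tibia", "tibiofemoral")
  hasChange <- any(!is.na(wide$change))

  strat <- function(outcome, gradeCol, levels) {
    do.call(rbind, lapply(regions, function(rg) {
      d <- wide[wide$region == rg & !is.na(wide[[outcome]]), , drop = FALSE]
      gs <- groupSummary(d, gradeCol, outcome, levels = levels)
      tab <- gs$table
      tab$region <- rg
      tab$outcome <- outcome
      tab$trend_p <- if (is.null(gs$trend)) NA_real_ else gs$trend$p
      tab[, c("region", "outcome", "grade", "n", "mean", "sd", "trend_p")]
    }))
  }

  srmTab <- NULL
  if (hasChange) {
    srmTab <- do.call(rbind, lapply(c("jsnProgressor", "klProgressor"),
                                    function(flag) {
      if (!flag %in% names(wide)) return(NULL)
      do.call(rbind, lapply(regions, function(rg) {
        d <- wide[wide$region == rg & !is.na(wide$change), , drop = FALSE]
        no <- d$change[!d[[flag]]]
        yes <- d$change[d[[flag]]]
        p <- if (length(no) >= 2 && length(yes) >= 2)
          twoSampleT(no, yes)$p else NA_real_
        m <- function(x) if (length(x)) mean(x) else NA_real_
        s <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
        sr <- function(x) if (length(x) >= 2 && stats::sd(x) > 0) srm(x)
              else NA_real_
        data.frame(
          region = rg, grading = sub("Progressor", "", flag),
          group = c("no_progression", "progression"),
          n = c(length(no), length(yes)),
          mean = c(m(no), m(yes)), sd = c(s(no), s(yes)),
          srm = c(sr(no), sr(yes)),
          t_test_p = p, row.names = NULL)
      }))
    }))
  }

  corTab <- NULL
  corCols <- intersect(c("hkaDeg", "jswBaselineMm", "jswChangeMm"),
                       names(wide))
  if (length(corCols)) {
    outcomes <- c("baseline", if (hasChange) "change")
    corTab <- do.call(rbind, lapply(outcomes, function(oc)
      do.call(rbind, lapply(regions, function(rg) {
        d <- wide[wide$region == rg & !is.na(wide[[oc]]), , drop = FALSE]
        rho <- vapply(corCols, function(cc) {
          ok <- !is.na(d[[cc]])
          if (sum(ok) < 3) return(NA_real_)
          tryCatch(spearmanCor(d[[oc]][ok], d[[cc]][ok]),
                   cdiUndefinedStatistic = function(e) NA_real_)
        }, numeric(1))
        cbind(data.frame(region = rg, outcome = oc), as.list(rho))
      }))))
  }

  pctTab <- NULL
  if ("jsnBaseline" %in% names(wide)) {
    bt <- strat("baseline", "jsnBaseline", 0:3)
    tf <- bt[bt$region == "tibiofemoral", ]
    ref <- tf$mean[tf$grade == 0]
    if (length(ref) == 1 && is.finite(ref) && ref > 0) {
      pctTab <- data.frame(
        grade = tf$grade, n = tf$n,
        pct_reduction_vs_grade0 = vapply(tf$mean, function(m)
          if (is.finite(m)) percentReduction(ref, m) else NA_integer_,
          integer(1)))
    }
  }

  list(
    baselineByJSN = if ("jsnBaseline" %in% names(wide))
      strat("baseline", "jsnBaseline", 0:3),
    changeByJSN = if (hasChange && "jsnBaseline" %in% names(wide))
      strat("change", "jsnBaseline", 0:3),
    baselineByKL = if ("klBaseline" %in% names(wide))
      strat("baseline", "klBaseline", 0:4),
    changeByKL = if (hasChange && "klBaseline" %in% names(wide))
      strat("change", "klBaseline", 0:4),
    srmByProgression = srmTab,
    correlations = corTab,
    percentReductionJSN = pctTab)
}
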