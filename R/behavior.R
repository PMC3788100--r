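#' Score a speech-in-noise intelligibility run
#'
#' The intelligibility score is the proportion of target words correctly
#' repeated in one listening configuration.
#'
#' @param correct Logical (or 0/1) vector of per-trial correctness flags.
#' @param subject,configuration Optional identifiers recorded on the
#'   result.
#' @return List with `subject`, `configuration`, `n_targets`, `n_correct`,
#'   `score` in `[0, 1]`.
#' @examples
#' score_intelligibility(c(rep(TRUE, 15), rep(FALSE, 5)))$score  # 0.75
#' @export
score_intelligibility <- function(correct, subject = NA_character_,
                                  configuration = NA_character_) {
  if (!length(correct)) stop("need at least one trial")
  flags <- as.logical(correct)
  if (anyNA(flags)) stop("'correct' must be logical or 0/1")
  list(subject = subject, configuration = configuration,
       n_targets = length(flags), n_correct = sum(flags),
       score = mean(flags))
}

#' Mixed Group-by-Configuration ANOVA with Bonferroni post-hoc
#'
#' Two-way mixed-design ANOVA of intelligibility scores with Group as the
#' between-subject factor and listening Configuration (e.g. dichotic,
#' monaural, spatialized) as the within-subject factor, on complete data
#' (every subject measured in every configuration). No sphericity
#' correction is applied. The post-hoc contrasts compare the groups within
#' each configuration by pooled two-sample t tests with the p-value
#' Bonferroni-multiplied by the number of configurations (capped at 1).
#'
#' @param scores Data frame with columns `id`, `group`, `configuration`,
#'   `score` (long format).
#' @return List with `anova` (effect, df1, df2, F, p), `posthoc`
#'   (per-configuration group comparison with `p_bonferroni`),
#'   `cell_means`.
#' @export
mixed_anova_group_by_config <- function(scores) {
  req <- c("id", "group", "configuration", "score")
  if (!all(req %in% names(scores)))
    stop("'scores' needs columns ", paste(req, collapse = ", "))
  scores$id <- factor(scores$id)
  scores$group <- factor(scores$group)
  scores$configuration <- factor(scores$configuration)
  tab <- table(scores$id, scores$configuration)
  if (any(tab != 1))
    stop("incomplete design: every subject needs exactly one score per configuration")
  fit <- stats::aov(score ~ group * configuration + Error(id/configuration),
                    data = scores)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: id"]][[1]])
  within <- as.data.frame(s[["Error: id:configuration"]][[1]])
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  an <- data.frame(
    effect = c("group", "configuration", "group:configuration"),
    ss = c(between["group", "Sum Sq"], within["configuration", "Sum Sq"],
           within["group:configuration", "Sum Sq"]),
    df1 = c(between["group", "Df"], within["configuration", "Df"],
            within["group:configuration", "Df"]),
    df2 = c(between["Residuals", "Df"], within["Residuals", "Df"],
            within["Residuals", "Df"]),
    err_ss = c(between["Residuals", "Sum Sq"], within["Residuals", "Sum Sq"],
               within["Residuals", "Sum Sq"]),
    stringsAsFactors = FALSE)
  an <- finalize_mixed_anova(an,
                             ss_total = sum((scores$score -
                                               mean(scores$score))^2),
                             ss_raw = sum(scores$score^2))

  cfgs <- levels(scores$configuration)
  k <- length(cfgs)
  gl <- levels(scores$group)
  posthoc <- NULL
  if (length(gl) == 2) {
    for (cf in cfgs) {
      x1 <- scores$score[scores$group == gl[1] & scores$configuration == cf]
      x2 <- scores$score[scores$group == gl[2] & scores$configuration == cf]
      r <- summary_two_sample_t(mean(x1), stats::sd(x1), length(x1),
                                mean(x2), stats::sd(x2), length(x2))
      posthoc <- rbind(posthoc, data.frame(
        configuration = cf, estimate = mean(x1) - mean(x2),
        t = r$t, df = r$df, p = r$p,
        p_bonferroni = min(1, k * r$p), stringsAsFactors = FALSE))
    }
  }
  cm <- stats::aggregate(score ~ group + configuration, data = scores,
                         FUN = mean)
  list(anova = an, posthoc = posthoc, cell_means = cm)
}

#' Group comparisons of summary-table measures
#'
#' Pooled two-sample Student t tests for a battery of measures reported
#' either as raw per-subject vectors or as `(mean, sd, n)` summaries, as
#' used for demographic/psychometric group-comparison tables.
#'
#' @param measures Named list; each element is either
#'   `list(x = <group-1 vector>, y = <group-2 vector>)` or
#'   `list(mean1 =, sd1 =, n1 =, mean2 =, sd2 =, n2 =)`.
#' @param welch Use Welch's t instead of the pooled form.
#' @return Data frame with `measure`, `t`, `df`, `p`, `significant`
#'   (p < 0.05).
#' @examples
#' table1_compare(list(age = list(mean1 = 23.29, sd1 = 6.08, n1 = 14,
#'                                mean2 = 26.07, sd2 = 6.19, n2 = 14)))
#' @export
table1_compare <- function(measures, welch = FALSE) {
  if (!length(measures) || is.null(names(measures)))
    stop("'measures' must be a nonempty named list")
  rows <- lapply(names(measures), function(nm) {
    m <- measures[[nm]]
    if (!is.null(m$x)) {
      r <- summary_two_sample_t(mean(m$x), stats::sd(m$x), length(m$x),
                                mean(m$y), stats::sd(m$y), length(m$y),
                                welch = welch)
    } else {
      r <- summary_two_sample_t(m$mean1, m$sd1, m$n1, m$mean2, m$sd2, m$n2,
                                welch = welch)
    }
    data.frame(measure = nm, t = r$t, df = r$df, p = r$p,
               significant = r$p < 0.05, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape a cohort subject table to long intelligibility scores
#'
#' @param subjects A cohort subject table with `score_*` columns.
#' @return Long data frame with `id`, `group`, `configuration`, `score`.
#' @export
scores_long <- function(subjects) {
  score_cols <- grep("^score_", names(subjects), value = TRUE)
  if (!length(score_cols)) stop("no score_* columns found")
  out <- do.call(rbind, lapply(score_cols, function(sc)
    data.frame(id = subjects$id, group = subjects$group,
               configuration = sub("^score_", "", sc),
               score = subjects[[sc]], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
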