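#' Coding-potential features of a set of sequences
#'
#' @param seqs named character vector of transcript sequences.
#' @param hexamer_tables as returned by [train_hexamer_tables()].
#' @return data.frame with `transcript_id`, `orf_length`, `orf_coverage`,
#'   `fickett`, `hexamer`.
#' @export
coding_features <- function(seqs, hexamer_tables) {
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    o <- longest_orf(s)
    data.frame(transcript_id = names(seqs)[i],
               orf_length = o$orf_length,
               orf_coverage = o$orf_coverage,
               fickett = fickett_score(s),
               hexamer = hexamer_score(s, hexamer_tables),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the logistic coding-potential model
#'
#' Logistic regression of coding status on log ORF length, ORF coverage,
#' Fickett score and hexamer score, fitted by maximum likelihood. The
#' decision cutoff is taken from the two-graph ROC on the training set: the
#' probability at which sensitivity and specificity intersect. A fixed
#' user-supplied cutoff (e.g. 0.365) overrides the ROC-derived one.
#'
#' @param features data.frame from [coding_features()].
#' @param labels logical or 0/1 vector, TRUE/1 = coding.
#' @param fixed_cutoff optional fixed coding-probability cutoff.
#' @return list of class `coding_model` with the fitted `glm`, `cutoff`,
#'   `cutoff_source`, and training `sensitivity`/`specificity` at the
#'   cutoff.
#' @export
fit_coding_model <- function(features, labels, fixed_cutoff = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stopf("coding model needs both classes in the training set")
  if (min(table(labels)) < 50L)
    stopf("coding model needs >= 50 examples per class (got %d)",
          min(table(labels)))
  df <- data.frame(label = labels,
                   log_orf = log(features$orf_length + 1),
                   coverage = features$orf_coverage,
                   fickett = features$fickett,
                   hexamer = features$hexamer)
  fit <- suppressWarnings(
    glm(label ~ log_orf + coverage + fickett + hexamer,
        data = df, family = binomial()))
  prob <- predict(fit, type = "response")
  if (is.null(fixed_cutoff)) {
    cutoff <- two_graph_roc_cutoff(prob, labels)
    src <- "two-graph ROC"
  } else {
    cutoff <- fixed_cutoff
    src <- "fixed"
  }
  sens <- mean(prob[labels == 1L] >= cutoff)
  spec <- mean(prob[labels == 0L] < cutoff)
  structure(list(fit = fit, cutoff = cutoff, cutoff_source = src,
                 sensitivity = sens, specificity = spec),
            class = "coding_model")
}

#' Two-graph ROC cutoff
#'
#' The probability threshold at which training sensitivity (coding called
#' coding) and specificity (non-coding called non-coding) intersect.
#'
#' @param prob fitted coding probabilities.
#' @param labels 0/1 coding labels.
#' @return numeric cutoff.
#' @export
two_graph_roc_cutoff <- function(prob, labels) {
  thr <- sort(unique(c(prob, 0, 1)))
  sens <- vapply(thr, function(t) mean(prob[labels == 1L] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(prob[labels == 0L] < t), numeric(1))
  thr[which.min(abs(sens - spec))]
}

#' Coding probability for new sequences
#' @param model a `coding_model`.
#' @param features data.frame from [coding_features()].
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
coding_probability <- function(model, features) {
  df <- data.frame(log_orf = log(features$orf_length + 1),
                   coverage = features$orf_coverage,
                   fickett = features$fickett,
                   hexamer = features$hexamer)
  as.numeric(predict(model$fit, newdata = df, type = "response"))
}
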