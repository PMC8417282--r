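# "Spectral phenotype" decoding: 4-class (area x group) classification
# of leads from their normalized session power spectra, with
# training-size sweeps, shuffled nulls and grouped leave-one-out
# designs.

PHENOTYPE_CLASSES <- c("ACC-control", "HPC-control", "ACC-STZ", "HPC-STZ")

#' Assemble the decoding dataset from lead spectra
#'
#' Features are each lead's normalized power restricted to
#' `feature_range` (default 1-50 Hz, avoiding line-noise frequencies)
#' and renormalized to sum to one; labels are the four (area x group)
#' classes; subject and session ids are carried for grouped designs.
#'
#' @param spectra list of `lead_spectrum` (one per lead, in lead order).
#' @param leads matching leads metadata table.
#' @param feature_range Hz interval of features.
#' @return `phenotype_dataset`: list with `features` [n_leads x n_freq],
#'   `labels` (factor over the 4 classes), `subject_id`, `session_id`.
#' @export
build_phenotype_dataset <- function(spectra, leads, feature_range = c(1, 50)) {
  if (length(spectra) != nrow(leads)) {
    stop("validation error: ", length(spectra), " spectra for ",
         nrow(leads), " leads", call. = FALSE)
  }
  ids <- vapply(spectra, function(s) s$lead_id, character(1))
  if (!all(is.na(ids)) && !identical(ids, leads$lead_id)) {
    ord <- match(leads$lead_id, ids)
    if (anyNA(ord)) stop("validation error: spectra and leads do not align by lead_id", call. = FALSE)
    spectra <- spectra[ord]
  }
  keep <- spectra[[1]]$freqs >= feature_range[1] & spectra[[1]]$freqs <= feature_range[2]
  feats <- t(vapply(spectra, function(s) {
    v <- s$norm_power[keep]
    v / sum(v)
  }, numeric(sum(keep))))
  colnames(feats) <- paste0("f", spectra[[1]]$freqs[keep])
  labels <- factor(paste(leads$area, leads$group, sep = "-"),
                   levels = PHENOTYPE_CLASSES)
  structure(list(features = feats, labels = labels,
                 subject_id = leads$subject_id, session_id = leads$session_id,
                 feature_range = feature_range),
            class = "phenotype_dataset")
}

# Fit the linear max-margin classifier and classify the test rows.
# Returns predicted labels and (optionally) posterior probabilities from
# Platt-style score calibration fitted on the training set.
fit_and_classify <- function(train_x, train_y, test_x, posterior = FALSE) {
  fit <- e1071::svm(train_x, droplevels(train_y), kernel = "linear", cost = 1,
                    scale = FALSE, probability = posterior)
  pred <- stats::predict(fit, test_x, probability = posterior)
  prob <- if (posterior) attr(pred, "probabilities") else NULL
  list(pred = factor(as.character(pred), levels = levels(train_y)), prob = prob)
}

# Classify each (true, predicted) pair as correct / wrong group /
# wrong area / wrong both.
misclass_type <- function(truth, pred) {
  ta <- sub("-.*", "", truth); tg <- sub(".*-", "", truth)
  pa <- sub("-.*", "", pred);  pg <- sub(".*-", "", pred)
  ifelse(ta == pa & tg == pg, "correct",
         ifelse(ta == pa, "wrong_group",
                ifelse(tg == pg, "wrong_area", "wrong_both")))
}

sample_training_idx <- function(labels, size) {
  unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    if (size >= length(idx)) {
      stop("sampling error: training size ", size, " >= ", length(idx),
           " leads in class ", cl, call. = FALSE)
    }
    sample(idx, size)
  }))
}

#' Training-size sweep of decoding accuracy
#'
#' For each training-set size and iteration, `size` leads per class are
#' drawn uniformly without replacement as the training set and all
#' remaining leads are classified. Held-out/training disjointness is
#' asserted on every iteration.
#'
#' @param ds a `phenotype_dataset` with all four classes present.
#' @param sizes training leads per class (default 5, 15, ..., 85).
#' @param n_iter iterations per size (default 1000).
#' @param seed master seed; iteration streams derive from it.
#' @param posterior also average Platt-calibrated posterior
#'   probabilities (slower; default TRUE).
#' @return list per size (named by size): `accuracy` (vector over
#'   iterations), `confusion` (mean row-stochastic 4x4), `posterior`
#'   (mean posterior per true class, or NULL), `misclass` (proportions
#'   of correct / wrong_group / wrong_area / wrong_both).
#' @export
training_size_sweep <- function(ds, sizes = seq(5, 85, by = 10), n_iter = 1000,
                                seed = 1, posterior = TRUE) {
  cls <- levels(ds$labels)
  out <- list()
  for (size in sizes) {
    acc <- numeric(n_iter)
    conf <- matrix(0, length(cls), length(cls), dimnames = list(cls, cls))
    post <- if (posterior) conf * 0 else NULL
    mis <- c(correct = 0, wrong_group = 0, wrong_area = 0, wrong_both = 0)
    for (it in seq_len(n_iter)) {
      set.seed(stream_seed(seed, "sweep", size, it))
      tr <- sample_training_idx(ds$labels, size)
      te <- setdiff(seq_along(ds$labels), tr)
      stopifnot(length(intersect(tr, te)) == 0)
      res <- fit_and_classify(ds$features[tr, ], ds$labels[tr],
                              ds$features[te, ], posterior)
      truth <- ds$labels[te]
      acc[it] <- mean(res$pred == truth)
      ctab <- table(truth, res$pred)
      conf <- conf + ctab / pmax(1, rowSums(ctab))
      if (posterior) {
        for (cl in cls) {
          sel <- truth == cl
          if (any(sel)) post[cl, ] <- post[cl, ] +
              colMeans(res$prob[sel, cls, drop = FALSE])
        }
      }
      mt <- table(factor(misclass_type(as.character(truth), as.character(res$pred)),
                         levels = names(mis)))
      mis <- mis + mt / length(te)
    }
    out[[as.character(size)]] <- list(
      size = size,
      accuracy = acc,
      confusion = conf / n_iter,
      posterior = if (posterior) post / n_iter else NULL,
      misclass = mis / n_iter)
  }
  out
}

#' Shuffled-label null of the decoding protocol
#'
#' Labels are permuted uniformly on every iteration before the
#' train/test split; with four balanced classes the held-out accuracy
#' concentrates at the 25% chance level and the three misclassification
#' outcomes are equally likely.
#'
#' @param ds a `phenotype_dataset`.
#' @param size training leads per class.
#' @param n_iter iterations.
#' @param seed master seed.
#' @return list: `accuracy` (vector), `mean`, `ci95` (2.5/97.5
#'   percentiles), `misclass` (mean outcome proportions).
#' @export
shuffled_null <- function(ds, size = 85, n_iter = 1000, seed = 1) {
  acc <- numeric(n_iter)
  mis <- c(correct = 0, wrong_group = 0, wrong_area = 0, wrong_both = 0)
  for (it in seq_len(n_iter)) {
    set.seed(stream_seed(seed, "null", size, it))
    lab <- ds$labels[sample(length(ds$labels))]
    tr <- sample_training_idx(lab, size)
    te <- setdiff(seq_along(lab), tr)
    stopifnot(length(intersect(tr, te)) == 0)
    res <- fit_and_classify(ds$features[tr, ], lab[tr], ds$features[te, ])
    acc[it] <- mean(res$pred == lab[te])
    mt <- table(factor(misclass_type(as.character(lab[te]), as.character(res$pred)),
                       levels = names(mis)))
    mis <- mis + mt / length(te)
  }
  list(accuracy = acc, mean = mean(acc),
       ci95 = as.numeric(quantile(acc, c(0.025, 0.975))),
       misclass = mis / n_iter)
}

#' Leave-one-subject/session-out decoding
#'
#' For each held-out unit (subject or session), repeatedly samples
#' `per_class` training leads per class from all other units, classifies
#' every lead of the held-out unit, and reports the mean proportion
#' correctly assigned to its (area x group) class.
#'
#' @param ds a `phenotype_dataset`.
#' @param group_key `"subject_id"` or `"session_id"`.
#' @param per_class training leads per class (default 40).
#' @param n_iter iterations per held-out unit (default 100).
#' @param seed master seed.
#' @return data.frame: unit, group, n_leads, accuracy (mean over
#'   iterations).
#' @export
leave_one_group_out <- function(ds, group_key = c("subject_id", "session_id"),
                                per_class = 40, n_iter = 100, seed = 1) {
  group_key <- match.arg(group_key)
  units <- unique(ds[[group_key]])
  rows <- list()
  for (u in units) {
    held <- which(ds[[group_key]] == u)
    rest <- setdiff(seq_along(ds$labels), held)
    acc <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      set.seed(stream_seed(seed, "logo", u, it))
      tr_local <- unlist(lapply(levels(ds$labels), function(cl) {
        idx <- rest[ds$labels[rest] == cl]
        if (length(idx) < per_class) {
          stop("sampling error: only ", length(idx), " leads of class ", cl,
               " outside unit ", u, call. = FALSE)
        }
        sample(idx, per_class)
      }))
      stopifnot(length(intersect(tr_local, held)) == 0)
      res <- fit_and_classify(ds$features[tr_local, ], ds$labels[tr_local],
                              ds$features[held, , drop = FALSE])
      acc[it] <- mean(res$pred == ds$labels[held])
    }
    rows[[u]] <- data.frame(unit = u,
                            group = unique(sub(".*-", "", ds$labels[held]))[1],
                            n_leads = length(held),
                            accuracy = mean(acc),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Lead spectra and decoding dataset of a whole cohort
#'
#' Convenience wrapper: per-lead session spectra (notch + short-time
#' PSD, normalized over `norm_range`), assembled into a
#' `phenotype_dataset` with features over `feature_range`.
#'
#' @param cohort named list of sessions from [generate_cohort()] /
#'   [read_cohort()].
#' @param norm_range,feature_range Hz intervals (see [session_psd()] and
#'   [build_phenotype_dataset()]).
#' @return a `phenotype_dataset`.
#' @export
cohort_phenotype_dataset <- function(cohort, norm_range = c(1, 100),
                                     feature_range = c(1, 50)) {
  spectra <- list(); leads <- list()
  for (sid in names(cohort)) {
    prof <- session_spectral_profile(cohort[[sid]], norm_range = norm_range)
    spectra <- c(spectra, prof$spectra)
    leads[[sid]] <- cohort[[sid]]$leads
  }
  build_phenotype_dataset(spectra, do.call(rbind, c(leads, list(make.row.names = FALSE))),
                          feature_range = feature_range)
}
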