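#' Sampler configuration
#'
#' Defaults encode the per-source mixing proportions used to balance the
#' four pseudo-sources (0.40 robot-OR-like, 0.30 egocentric-like, 0.20
#' scene-graph-like, 0.10 multi-view-like) and the benchmark split sizes,
#' which are scale-configurable.
#'
#' @param dataset_weights named proportions per source tag, summing to 1
#' @param target_sizes named split sizes (`train`, `val`, `test`)
#' @param answer_bins binning widths used to define "answer frequency" for
#'   continuous answers: `m` (meters), `s` (seconds), `percent`, and
#'   `grid_px` (image-grid cell size for boxes and 2D points)
#' @param seed integer seed for the weighted draw
#' @return a list of class `orqa_sampler_config`
#' @export
sampler_config <- function(dataset_weights = c(mmor_like = 0.40,
                                               egosurgery_like = 0.30,
                                               fourdor_like = 0.20,
                                               mvor_like = 0.10),
                           target_sizes = c(train = 2000, val = 200,
                                            test = 200),
                           answer_bins = list(m = 0.25, s = 10, percent = 10,
                                              grid_px = 80),
                           seed = 1) {
  stopifnot(abs(sum(dataset_weights) - 1) < 1e-9, all(dataset_weights >= 0),
            all(target_sizes >= 1), !is.null(names(dataset_weights)),
            !is.null(names(target_sizes)))
  structure(list(dataset_weights = dataset_weights,
                 target_sizes = target_sizes,
                 answer_bins = answer_bins, seed = as.integer(seed)),
            class = "orqa_sampler_config")
}

#' Bin an answer for frequency counting
#'
#' Categorical answers (counts, labels, sets, sequences, triplet lists,
#' text) bin to their canonical serialization; scalars bin by fixed width
#' per unit (`floor(value / width)`); boxes and 2D points bin by the
#' image-grid cell containing their center; 3D points by a metric grid.
#'
#' @param answer an `orqa_answer`
#' @param spec binning widths (see [sampler_config()]'s `answer_bins`)
#' @return a character bin key
#' @export
bin_answer <- function(answer, spec = sampler_config()$answer_bins) {
  stopifnot(inherits(answer, "orqa_answer"))
  v <- answer$value
  switch(answer$tag,
    scalar = {
      w <- spec[[answer$units]]
      sprintf("%s:%d", answer$units, floor(v / w))
    },
    box = {
      g <- spec$grid_px
      sprintf("cell:%d,%d", floor((v[1] + v[3]) / 2 / g),
              floor((v[2] + v[4]) / 2 / g))
    },
    point2 = sprintf("cell:%d,%d", floor(v[1] / spec$grid_px),
                     floor(v[2] / spec$grid_px)),
    point3 = sprintf("vox:%d,%d,%d", floor(v[1] / spec$m),
                     floor(v[2] / spec$m), floor(v[3] / spec$m)),
    serialize_answer(answer)
  )
}

# Vectorized binning over a pool: operates on the serialized answer_text
# column, grouped by tag, to keep 10^5-row pools fast.
bin_pool <- function(pool, spec = sampler_config()$answer_bins) {
  bins <- pool$answer_text
  tag <- pool$answer_tag
  sc <- which(tag == "scalar")
  if (length(sc)) {
    w <- unlist(spec[pool$units[sc]], use.names = FALSE)
    bins[sc] <- sprintf("%s:%d", pool$units[sc],
                        floor(as.numeric(pool$answer_text[sc]) / w))
  }
  num_cols <- function(idx, n) {
    m <- matrix(as.numeric(unlist(data.table::tstrsplit(
      pool$answer_text[idx], ",", fixed = TRUE)[seq_len(n)])), ncol = n)
    m
  }
  bx <- which(tag == "box")
  if (length(bx)) {
    m <- num_cols(bx, 4L)
    g <- spec$grid_px
    bins[bx] <- sprintf("cell:%d,%d", floor((m[, 1] + m[, 3]) / 2 / g),
                        floor((m[, 2] + m[, 4]) / 2 / g))
  }
  p2 <- which(tag == "point2")
  if (length(p2)) {
    m <- num_cols(p2, 2L)
    bins[p2] <- sprintf("cell:%d,%d", floor(m[, 1] / spec$grid_px),
                        floor(m[, 2] / spec$grid_px))
  }
  p3 <- which(tag == "point3")
  if (length(p3)) {
    m <- num_cols(p3, 3L)
    bins[p3] <- sprintf("vox:%d,%d,%d", floor(m[, 1] / spec$m),
                        floor(m[, 2] / spec$m), floor(m[, 3] / spec$m))
  }
  bins
}

#' Fit question/answer frequency tables on a pool
#'
#' Counts how often each `(task, template_id)` question pattern and each
#' `(task, answer_bin)` answer value occur in the pool; the inverse of
#' these counts drives diversity sampling.
#'
#' @param pool a QA `data.table`
#' @param spec answer binning widths
#' @return an `orqa_freq` object
#' @export
fit_frequency <- function(pool, spec = sampler_config()$answer_bins) {
  pool <- data.table::as.data.table(pool)
  bin <- bin_pool(pool, spec)
  qtab <- pool[, list(q_count = .N), by = c("task", "template_id")]
  atab <- data.table::data.table(task = pool$task, answer_bin = bin)[
    , list(a_count = .N), by = c("task", "answer_bin")]
  structure(list(qtab = qtab, atab = atab, spec = spec, n = nrow(pool)),
            class = "orqa_freq")
}

#' Inverse-frequency sampling weights
#'
#' Weight of a QA pair is proportional to
#' `1 / (question_count * answer_bin_count)`: pairs with rare question
#' patterns and rare answers are prioritized, emphasizing long-tail
#' patterns. Strictly positive; errors if the pool contains a key the
#' frequency table has never seen.
#'
#' @param pool a QA `data.table` (any row order; weights are
#'   order-invariant)
#' @param freq an `orqa_freq` fitted on the same pool
#' @return numeric weights aligned with `pool` rows
#' @export
sampling_weight <- function(pool, freq) {
  stopifnot(inherits(freq, "orqa_freq"))
  pool <- data.table::as.data.table(pool)
  qn <- freq$qtab[pool, q_count, on = c("task", "template_id")]
  ab <- data.table::data.table(task = pool$task,
                               answer_bin = bin_pool(pool, freq$spec))
  an <- freq$atab[ab, a_count, on = c("task", "answer_bin")]
  if (anyNA(qn) || anyNA(an))
    stop("pool contains keys unseen by the frequency table ",
         "(pool/table mismatch)")
  1 / (as.numeric(qn) * as.numeric(an))
}

#' Diversity-aware benchmark sampling
#'
#' Reduces a large QA pool to a benchmark by stratified weighted sampling
#' without replacement: first by split (split boundaries are never
#' crossed), then by source with target proportions equal to the
#' configured dataset weights, then by task with equal quotas within each
#' source (remainders spread deterministically over task-name order), and
#' finally weighted by [sampling_weight()] within each stratum using the
#' exponential-key scheme, which is reproducible under a seed and
#' independent of pool row order. An exhausted stratum contributes all its
#' pairs and is recorded as a shortfall in the manifest.
#'
#' @param pool a QA `data.table` carrying `split` labels
#' @param config an [sampler_config()]
#' @return an `orqa_benchmark`: list with `pairs` (sampled rows) and
#'   `manifest` (per-stratum targets, draws and shortfalls)
#' @export
sample_benchmark <- function(pool, config = sampler_config()) {
  stopifnot(inherits(config, "orqa_sampler_config"))
  pool <- data.table::as.data.table(pool)
  stopifnot("split" %in% names(pool), !anyNA(pool$split))
  data.table::setorderv(pool, "qa_id")  # draw is row-order independent
  freq <- fit_frequency(pool, config$answer_bins)
  w <- sampling_weight(pool, freq)

  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  # one exponential key per pair; weighted sampling without replacement =
  # take the smallest keys e_i / w_i within each stratum
  keys <- stats::rexp(nrow(pool)) / w

  take <- logical(nrow(pool))
  manifest <- list()
  splits <- intersect(names(config$target_sizes), unique(pool$split))
  for (sp in splits) {
    sp_idx <- which(pool$split == sp)
    srcs <- intersect(names(config$dataset_weights),
                      unique(pool$source_tag[sp_idx]))
    src_quota <- largest_remainder(config$target_sizes[[sp]],
                                   config$dataset_weights[srcs])
    for (src in srcs) {
      src_idx <- sp_idx[pool$source_tag[sp_idx] == src]
      tasks <- sort(unique(pool$task[src_idx]))
      task_quota <- largest_remainder(src_quota[[src]],
                                      stats::setNames(rep(1, length(tasks)),
                                                      tasks))
      for (tk in tasks) {
        idx <- src_idx[pool$task[src_idx] == tk]
        quota <- task_quota[[tk]]
        avail <- length(idx)
        drawn <- min(quota, avail)
        if (drawn > 0) {
          chosen <- if (avail <= quota) idx
                    else idx[order(keys[idx])[seq_len(quota)]]
          take[chosen] <- TRUE
        }
        manifest[[length(manifest) + 1L]] <- data.table::data.table(
          split = sp, source_tag = src, task = tk,
          target = quota, drawn = drawn, shortfall = quota - drawn)
      }
    }
  }
  manifest <- data.table::rbindlist(manifest)
  short <- manifest[manifest$shortfall > 0]
  if (nrow(short) > 0)
    message("sampler shortfall in ", nrow(short), " strata (",
            sum(short$shortfall), " pairs); see manifest")
  structure(list(pairs = pool[take], manifest = manifest, config = config),
            class = "orqa_benchmark")
}

#' @export
print.orqa_benchmark <- function(x, ...) {
  cat(sprintf("<orqa_benchmark> %d pairs\n", nrow(x$pairs)))
  print(data.table::dcast(x$pairs[, .N, by = c("split", "source_tag")],
                          source_tag ~ split, value.var = "N", fill = 0L))
  invisible(x)
}
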