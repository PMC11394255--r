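# Simulated paired reader study under the equal-variance Gaussian
# signal-detection model: on each trial a reader observes evidence
# x ~ N(0, 1) for a nevus and x ~ N(d', 1) for a melanoma and responds
# "melanoma" iff x > criterion. The without-cue and with-cue conditions
# share the truth labels per image but use the reader's condition-specific
# discriminability, mirroring a paired study design in which every image is
# read twice.

#' Specify a simulated paired reader study
#'
#' @param n_readers number of readers.
#' @param n_melanoma,n_nevus images per class. Defaults 38 and 40 are the
#'   per-class denominators implied by the published study table this package
#'   reproduces.
#' @param dprime_without,dprime_with per-reader discriminability (recycled to
#'   `n_readers`), each `>= 0`, in the without-cue / with-cue condition.
#' @param criterion per-reader decision criterion (recycled). Default
#'   `dprime_without / 2`, i.e. unbiased at baseline.
#' @param seed integer seed.
#' @return object of class `reader_spec`.
#' @export
reader_spec <- function(n_readers = 10L,
                        n_melanoma = 38L,
                        n_nevus = 40L,
                        dprime_without = 0.94,
                        dprime_with = 1.41,
                        criterion = NULL,
                        seed = 1L) {
  stopifnot(n_readers >= 1, n_melanoma >= 1, n_nevus >= 1,
            all(dprime_without >= 0), all(dprime_with >= 0))
  dprime_without <- rep_len(dprime_without, n_readers)
  dprime_with <- rep_len(dprime_with, n_readers)
  if (is.null(criterion)) criterion <- dprime_without / 2
  criterion <- rep_len(criterion, n_readers)
  structure(
    list(n_readers = as.integer(n_readers),
         n_melanoma = as.integer(n_melanoma),
         n_nevus = as.integer(n_nevus),
         dprime_without = dprime_without,
         dprime_with = dprime_with,
         criterion = criterion,
         seed = as.integer(seed)),
    class = "reader_spec"
  )
}

#' Simulate paired reader responses
#'
#' Draws binary melanoma/nevus decisions for every reader and image in both
#' conditions from the equal-variance Gaussian evidence model of the
#' [reader_spec()].
#'
#' @param spec a [reader_spec()].
#' @return a tibble (response table) with columns `reader_id`, `image_id`,
#'   `truth`, `decision_without`, `decision_with`; labels are `"melanoma"` /
#'   `"nevus"`.
#' @export
#' @examples
#' tab <- simulate_reader_responses(reader_spec(n_readers = 2, seed = 7))
#' table(tab$truth, tab$decision_without)
simulate_reader_responses <- function(spec) {
  stopifnot(inherits(spec, "reader_spec"))
  set.seed(spec$seed)
  n_img <- spec$n_melanoma + spec$n_nevus
  truth <- rep(c("melanoma", "nevus"), c(spec$n_melanoma, spec$n_nevus))
  image_id <- sprintf("img_%03d", seq_len(n_img))
  is_pos <- truth == "melanoma"

  out <- vector("list", spec$n_readers)
  for (i in seq_len(spec$n_readers)) {
    decide <- function(dprime) {
      x <- stats::rnorm(n_img, mean = ifelse(is_pos, dprime, 0), sd = 1)
      ifelse(x > spec$criterion[i], "melanoma", "nevus")
    }
    out[[i]] <- tibble::tibble(
      reader_id = sprintf("reader_%02d", i),
      image_id = image_id,
      truth = truth,
      decision_without = decide(spec$dprime_without[i]),
      decision_with = decide(spec$dprime_with[i])
    )
  }
  do.call(rbind, out)
}
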