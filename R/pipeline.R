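#' Prepare labelled pair instances from corpus files
#'
#' Convenience wrapper for the full preprocessing pipeline: read the XML
#' corpus and the CoNLL-U parses, build pair instances, anonymize drug
#' mentions and attach shortest dependency paths.
#'
#' @param xml path to an XML file or directory of XML files.
#' @param conllu path to the CoNLL-U file.
#' @param anonymize_others blind non-target drug mentions with `drugn`.
#' @return an instance tibble ready for [ddi_fit()] / [predict.ddi_model()].
#' @export
#' @examples
#' d <- tempfile(); dir.create(d)
#' generate_corpus(synthetic_spec(n_sentences = 5), out_dir = d)
#' inst <- prepare_instances(file.path(d, "corpus.xml"),
#'                           file.path(d, "parses.conllu"))
#' inst$label
prepare_instances <- function(xml, conllu, anonymize_others = TRUE) {
  corpus <- read_ddi_corpus(xml)
  parses <- read_conllu(conllu)
  build_instances(corpus, parses) |>
    anonymize_instances(anonymize_others = anonymize_others) |>
    attach_sdp()
}

#' Stratified train/test split of an instance tibble
#'
#' Splits by label so that rare positive classes appear on both sides.
#'
#' @param instances instance tibble.
#' @param prop proportion assigned to the training side.
#' @param seed RNG seed.
#' @return list with `train` and `test` tibbles.
#' @export
split_instances <- function(instances, prop = 0.8, seed = 1L) {
  take <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(instances)), instances$label),
                  function(ix) {
                    k <- max(1L, round(length(ix) * prop))
                    sample(ix, k)
                  }))
  })
  list(train = instances[sort(take), ],
       test = instances[setdiff(seq_len(nrow(instances)), take), ])
}
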