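Package: ddisdp
Title: Drug-Drug Interaction Extraction with Hierarchical Recurrent
    Networks over Sentence Sequence and Shortest Dependency Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts and classifies drug-drug interactions (DDIs) from
    sentence-level annotated biomedical corpora in the DDIExtraction-2013
    XML dialect. Candidate drug pairs are encoded with four-channel token
    embeddings (word, part-of-speech and two relative-position channels),
    weighted by an embedding-level entity attention mechanism, split into
    three context subsequences around the two target drug mentions, and
    combined with the shortest dependency path (SDP) between the mentions
    extracted from CoNLL-U parses. A hierarchical bidirectional recurrent
    network (LSTM, GRU or simple cells) encodes the subsequences and the
    SDP with bottom encoders and integrates them with a top encoder and a
    softmax classifier over the five DDI classes (Negative, Advice,
    Effect, Mechanism, Int). Includes a seeded synthetic corpus generator
    with planted, SDP-localised class signals for end-to-end testing,
    micro-averaged precision/recall/F evaluation in the DDIExtraction-2013
    convention, broom-style tidiers, ggplot2 autoplot methods, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
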