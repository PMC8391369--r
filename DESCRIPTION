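Package: recuerda
Title: Personalized Reminiscence-Therapy Dialogue Engine and Evaluation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A text-mode conversational engine for delivering personalized
    reminiscence therapy to people with early-stage Alzheimer's disease.
    Conversations are driven by an AIML-subset knowledge base of 20 Spanish
    dialogue contexts whose templates are personalized from a 32-question
    patient profile (personal information, family relationships, life history
    and lifestyle). The package ships the knowledge base, a profile store,
    Spanish text normalization, a dialogue manager with non-repetitive
    seeded response selection, pluggable speech adapter contracts, seeded
    synthetic fixtures (profiles, simulated users, evaluation dialogue sets,
    corrupted transcript pairs), and the quantitative evaluation machinery:
    word error rate with substitution/insertion/deletion decomposition,
    Voted Appropriateness (Rvoted/Rmax) vote aggregation with tie-inclusive
    agreement percentages, Pearson correlation, and star-rating summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
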