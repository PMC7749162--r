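# Builds inst/extdata/synthetic_lexicon.tsv, the bundled SYNTHETIC fixture
# lexicon. Terms are common condition/intervention names; the source
# assignments and identifiers are fabricated (this is not real MeSH, MedDRA
# or SNOMED-CT content). Sources deliberately overlap so that union-coverage
# accounting differs from any single source.
suppressPackageStartupMessages(library(tibble))
suppressPackageStartupMessages(library(dplyr))

conditions <- c(
  "Diabetes Mellitus", "Hypertension", "Asthma", "Breast Neoplasms",
  "Lung Neoplasms", "Depressive Disorder", "Alzheimer Disease",
  "Parkinson Disease", "Rheumatoid Arthritis", "Osteoarthritis",
  "Chronic Obstructive Pulmonary Disease", "Heart Failure",
  "Myocardial Infarction", "Stroke", "Obesity", "Anxiety Disorders",
  "Schizophrenia", "Epilepsy", "Multiple Sclerosis", "Psoriasis",
  "Atopic Dermatitis", "Crohn Disease", "Ulcerative Colitis",
  "Hepatitis C", "HIV Infections", "Influenza", "Tuberculosis",
  "Malaria", "Chronic Kidney Disease", "Anemia", "Leukemia",
  "Lymphoma", "Melanoma", "Prostatic Neoplasms", "Colorectal Neoplasms",
  "Pancreatic Neoplasms", "Ovarian Neoplasms", "Cystic Fibrosis",
  "Sickle Cell Disease", "Migraine Disorders"
)

interventions <- c(
  "Aspirin", "Metformin", "Insulin", "Atorvastatin", "Lisinopril",
  "Amlodipine", "Omeprazole", "Sertraline", "Fluoxetine", "Gabapentin",
  "Ibuprofen", "Acetaminophen", "Prednisone", "Albuterol", "Warfarin",
  "Rituximab", "Trastuzumab", "Pembrolizumab", "Cisplatin", "Paclitaxel",
  "Influenza Vaccine", "BCG Vaccine", "Insulin Pump", "Cardiac Pacemaker",
  "Coronary Stent", "Cognitive Behavioral Therapy", "Exercise Program",
  "Dietary Counseling", "Radiotherapy", "Proton Beam Therapy",
  "Gene Transfer Therapy", "Vitamin D Supplement", "Omega-3 Supplement",
  "Magnetic Resonance Imaging", "Computed Tomography", "Placebo"
)

terms <- c(conditions, interventions)
n <- length(terms)

rows <- list()
add <- function(source, idx, prefix) {
  rows[[length(rows) + 1]] <<- tibble(
    source_id = source,
    preferred_name = terms[idx],
    identifier = sprintf("%s:%06d", prefix, idx)
  )
}

# MESH covers most terms; MEDDRA covers conditions with a different tail;
# SNOMEDCT covers a partially overlapping subset including some terms
# absent from both others, so union > max(single source).
add("MESH",     setdiff(seq_len(n), c(seq(5, n, by = 7))), "D")
add("MEDDRA",   seq(1, length(conditions), by = 2), "MDR")
add("SNOMEDCT", sort(unique(c(seq(2, n, by = 3), seq(5, n, by = 7)))), "SCT")

lex <- bind_rows(rows) %>% arrange(source_id, preferred_name)

# a duplicated preferred name within one source, to exercise identifier-set
# merging on load
lex <- bind_rows(lex, tibble(source_id = "MESH",
                             preferred_name = "Aspirin",
                             identifier = "D:900001"))

readr::write_tsv(lex, "inst/extdata/synthetic_lexicon.tsv")
cat("terms:", n, "rows:", nrow(lex), "\n")
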