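# Builds inst/extdata/field_registry.tsv, the machine-readable ClinicalTrials.gov
# data-dictionary registry. Run from the package root:
#   Rscript data-raw/field_registry.R
#
# Counts asserted at the bottom are the structural facts the audit relies on:
#   149 dictionary elements; 28 audited FDAAA801 fields (composite groups counted once);
#   13 excluded FDAAA801 fields (5 conditionally-unknowable + 3 internal + 3 post-2017
#   additions + 2 administrative); 16 enumerated fields (9 XSD-typed, 7 untyped);
#   11 Boolean, 3 integer, 4 date, 2 age fields.
#
# NOTE on the study-phase value set: the dictionary's printed list omits the plain
# "Phase 2" value even though both "Phase 1/Phase 2" and "Phase 2/Phase 3" appear;
# "Phase 2" demonstrably occurs in registry records and is included here. The
# omission is treated as a typographical artifact of the printed list.

suppressPackageStartupMessages(library(tibble))
suppressPackageStartupMessages(library(dplyr))

rows <- list()
spec <- function(dictionary_name, xml_path, value_kind = "free_text",
                 allowed_dict = "", allowed_record = "",
                 multiplicity = "single", xsd_typed = FALSE,
                 fdaaa_field = "", who_field = "",
                 requirement = "optional", condition_id = "",
                 final_rule_only = FALSE,
                 applicability = "interventional|observational|expanded_access",
                 exclusion_reason = "none", parent = "") {
  rows[[length(rows) + 1L]] <<- tibble(
    dictionary_name = dictionary_name, xml_path = xml_path,
    value_kind = value_kind, allowed_dict = allowed_dict,
    allowed_record = allowed_record, multiplicity = multiplicity,
    xsd_typed = xsd_typed, fdaaa_field = fdaaa_field, who_field = who_field,
    requirement = requirement, condition_id = condition_id,
    final_rule_only = final_rule_only, applicability = applicability,
    exclusion_reason = exclusion_reason, parent = parent)
}

INT <- "interventional"
ALL <- "interventional|observational|expanded_access"
IO  <- "interventional|observational"

status_set <- paste("Not yet recruiting", "Recruiting", "Enrolling by invitation",
                    "Active, not recruiting", "Completed", "Suspended", "Terminated",
                    "Withdrawn", sep = "|")

## ---- audited FDAAA801 fields (28 groups) -----------------------------------

spec("brief title", "brief_title", "free_text", requirement = "always",
     fdaaa_field = "Brief Title", who_field = "Public Title", applicability = ALL)
spec("brief summary", "brief_summary/textblock", "free_text", requirement = "always",
     fdaaa_field = "Brief Summary", applicability = ALL)
spec("study phase", "phase", "enumerated",
     allowed_dict = "N/A|Early Phase 1|Phase 1|Phase 1/Phase 2|Phase 2|Phase 2/Phase 3|Phase 3|Phase 4",
     xsd_typed = TRUE, requirement = "always", fdaaa_field = "Study Phase",
     applicability = INT)
spec("study type", "study_type", "enumerated",
     allowed_dict = "Interventional|Observational|Observational [Patient Registry]|Expanded Access",
     xsd_typed = TRUE, requirement = "always", fdaaa_field = "Study Type",
     who_field = "Study Type", applicability = ALL)
spec("condition", "condition", "ontology_recommended", multiplicity = "multiple",
     requirement = "always", fdaaa_field = "Primary Disease or Condition Being Studied",
     who_field = "Health Condition(s) or Problem(s) Studied", applicability = ALL)
spec("intervention name", "intervention/intervention_name", "free_text",
     multiplicity = "multiple", requirement = "always",
     fdaaa_field = "Intervention Name(s)", who_field = "Intervention(s)",
     applicability = ALL)
spec("intervention type", "intervention/intervention_type", "enumerated",
     allowed_dict = "Drug|Device|Biologic/Vaccine|Procedure/Surgery|Radiation|Behavioral|Genetic|Dietary Supplement|Combination Product|Diagnostic Test|Other",
     multiplicity = "multiple", xsd_typed = TRUE, requirement = "always",
     fdaaa_field = "Intervention Type", applicability = ALL)
spec("eligibility criteria", "eligibility/criteria/textblock", "free_text",
     requirement = "always", fdaaa_field = "Eligibility Criteria",
     who_field = "Key Inclusion and Exclusion Criteria", applicability = ALL)
spec("sex", "eligibility/gender", "enumerated", allowed_dict = "All|Male|Female",
     xsd_typed = TRUE, requirement = "always", fdaaa_field = "Sex/Gender",
     applicability = ALL)
spec("age limits", "eligibility", "composite", requirement = "always",
     fdaaa_field = "Age Limits", applicability = ALL)
spec("minimum age", "eligibility/minimum_age", "age", xsd_typed = TRUE,
     requirement = "always", applicability = ALL, parent = "age limits")
spec("maximum age", "eligibility/maximum_age", "age", xsd_typed = TRUE,
     requirement = "always", applicability = ALL, parent = "age limits")
spec("overall recruitment status", "overall_status", "enumerated",
     allowed_dict = status_set, xsd_typed = TRUE, requirement = "always",
     fdaaa_field = "Overall Recruitment Status", who_field = "Recruitment Status",
     applicability = ALL)
spec("sponsor", "sponsors/lead_sponsor/agency", "free_text", requirement = "always",
     fdaaa_field = "Name of the Sponsor", who_field = "Primary Sponsor",
     applicability = ALL)
spec("responsible party type", "responsible_party/responsible_party_type",
     "enumerated", allowed_dict = "Sponsor|Principal Investigator|Sponsor-Investigator",
     xsd_typed = TRUE, requirement = "always",
     fdaaa_field = "Responsible Party, by Official Title", applicability = ALL)
spec("secondary id", "id_info/secondary_id", "free_text", multiplicity = "multiple",
     requirement = "always", fdaaa_field = "Secondary ID",
     who_field = "Secondary Identifying Numbers", applicability = ALL)
spec("official title", "official_title", "free_text", requirement = "always",
     fdaaa_field = "Official Title", who_field = "Scientific Title",
     final_rule_only = TRUE, applicability = ALL)
spec("primary purpose", "study_design_info/primary_purpose", "enumerated",
     allowed_dict = "Treatment|Prevention|Diagnostic|Supportive Care|Screening|Health Services Research|Basic Science|Device Feasibility|Other",
     requirement = "always", fdaaa_field = "Primary Purpose", applicability = INT)
spec("study design", "study_design_info", "composite", requirement = "always",
     fdaaa_field = "Study Design", who_field = "Study Design", applicability = INT)
spec("interventional study model", "study_design_info/intervention_model",
     "enumerated",
     allowed_dict = "Single Group|Parallel|Crossover|Factorial|Sequential",
     allowed_record = "Single Group Assignment|Parallel Group Assignment|Crossover Assignment|Factorial Assignment|Sequential Assignment",
     requirement = "always", applicability = INT, parent = "study design")
spec("allocation", "study_design_info/allocation", "enumerated",
     allowed_dict = "N/A|Randomized|Nonrandomized", requirement = "always",
     applicability = INT, parent = "study design")
spec("masking", "study_design_info/masking", "enumerated",
     allowed_dict = "Participant|Care Provider|Investigator|Outcomes Assessor|No Masking",
     allowed_record = "pattern:masking", requirement = "always",
     applicability = INT, parent = "study design")
spec("number of arms", "number_of_arms", "integer", xsd_typed = TRUE,
     requirement = "always", applicability = INT, parent = "study design")
spec("arm information", "arm_group", "composite", multiplicity = "multiple",
     requirement = "always", applicability = INT, parent = "study design")
spec("arm label", "arm_group/arm_group_label", "free_text",
     multiplicity = "multiple", requirement = "always", applicability = INT,
     parent = "arm information")
spec("arm type", "arm_group/arm_group_type", "enumerated",
     allowed_dict = "Experimental|Active Comparator|Placebo Comparator|Sham Comparator|No Intervention|Other",
     multiplicity = "multiple", requirement = "always", applicability = INT,
     parent = "arm information")
spec("arm description", "arm_group/description", "free_text",
     multiplicity = "multiple", applicability = INT, parent = "arm information")
spec("intervention description", "intervention/description", "free_text",
     multiplicity = "multiple", requirement = "always",
     fdaaa_field = "Intervention Description", applicability = ALL)
spec("study start date", "start_date", "date", xsd_typed = TRUE,
     requirement = "always", fdaaa_field = "Study Start Date",
     who_field = "Date of First Enrollment", final_rule_only = TRUE,
     applicability = ALL)
spec("primary completion date", "primary_completion_date", "date",
     xsd_typed = TRUE, requirement = "always",
     fdaaa_field = "Primary Completion Date", applicability = IO)
spec("study completion date", "completion_date", "date", xsd_typed = TRUE,
     requirement = "always", fdaaa_field = "Study Completion Date",
     final_rule_only = TRUE, applicability = ALL)
spec("enrollment", "enrollment", "integer", xsd_typed = TRUE,
     requirement = "always", fdaaa_field = "Enrollment",
     who_field = "Target Sample Size", applicability = IO)
spec("primary outcome measure", "primary_outcome", "composite",
     multiplicity = "multiple", requirement = "always",
     fdaaa_field = "Primary Outcome Measure Information",
     who_field = "Primary Outcome(s)", applicability = IO)
spec("outcome measure", "primary_outcome/measure", "free_text",
     multiplicity = "multiple", requirement = "always", applicability = IO,
     parent = "primary outcome measure")
spec("outcome time frame", "primary_outcome/time_frame", "free_text",
     multiplicity = "multiple", requirement = "always", applicability = IO,
     parent = "primary outcome measure")
spec("outcome description", "primary_outcome/description", "free_text",
     multiplicity = "multiple", applicability = IO,
     parent = "primary outcome measure")
spec("accepts healthy volunteers", "eligibility/healthy_volunteers", "free_text",
     requirement = "always", fdaaa_field = "Accepts Healthy Volunteers",
     applicability = IO)
spec("why study stopped", "why_stopped", "free_text", requirement = "conditional",
     fdaaa_field = "Why Study Stopped", condition_id = "cond_study_stopped",
     final_rule_only = TRUE, applicability = ALL)
spec("individual site status", "location/status", "enumerated",
     allowed_dict = status_set, multiplicity = "multiple", xsd_typed = TRUE,
     requirement = "conditional", fdaaa_field = "Individual Site Status",
     condition_id = "cond_has_locations", applicability = IO)
spec("availability of expanded access", "has_expanded_access", "boolean",
     xsd_typed = TRUE, requirement = "always",
     fdaaa_field = "Availability of Expanded Access", applicability = INT)
spec("facility information", "location", "composite", multiplicity = "multiple",
     requirement = "always", fdaaa_field = "Facility Information",
     who_field = "Countries of Recruitment", applicability = IO)
spec("facility name", "location/facility/name", "free_text",
     multiplicity = "multiple", requirement = "always", applicability = IO,
     parent = "facility information")
spec("facility city", "location/facility/address/city", "free_text",
     multiplicity = "multiple", requirement = "always", applicability = IO,
     parent = "facility information")
spec("facility country", "location/facility/address/country", "free_text",
     multiplicity = "multiple", requirement = "always", applicability = IO,
     parent = "facility information")
spec("facility contact", "location/contact", "composite",
     multiplicity = "multiple", applicability = IO,
     parent = "facility information")

## ---- FDAAA801 fields excluded from the completeness audit (13) -------------

spec("pediatric postmarket surveillance", "oversight_info/is_ppsd", "boolean",
     xsd_typed = TRUE, fdaaa_field = "Pediatric Postmarket Surveillance",
     requirement = "excluded_from_audit", exclusion_reason = "conditional_unknowable")
spec("product export", "oversight_info/is_us_export", "boolean", xsd_typed = TRUE,
     fdaaa_field = "Product Manufactured in or Exported from the U.S.",
     requirement = "excluded_from_audit", exclusion_reason = "conditional_unknowable")
spec("other intervention names", "intervention/other_name", "free_text",
     multiplicity = "multiple", fdaaa_field = "Other Names for Interventions",
     requirement = "excluded_from_audit", exclusion_reason = "conditional_unknowable")
spec("post prior to fda approval", "post_prior_to_fda_approval", "free_text",
     fdaaa_field = "Post Prior to FDA Approval/Clearance",
     requirement = "excluded_from_audit", exclusion_reason = "conditional_unknowable")
spec("secondary outcome measure", "secondary_outcome", "composite",
     multiplicity = "multiple",
     fdaaa_field = "Secondary Outcome Measure Information",
     who_field = "Key Secondary Outcomes",
     requirement = "excluded_from_audit", exclusion_reason = "conditional_unknowable")
spec("secondary outcome measure name", "secondary_outcome/measure", "free_text",
     multiplicity = "multiple", parent = "secondary outcome measure")
spec("secondary outcome time frame", "secondary_outcome/time_frame", "free_text",
     multiplicity = "multiple", parent = "secondary outcome measure")
spec("secondary outcome description", "secondary_outcome/description", "free_text",
     multiplicity = "multiple", parent = "secondary outcome measure")

spec("fda ind or ide", "fda_ind_ide", "free_text", fdaaa_field = "FDA IND or IDE",
     requirement = "excluded_from_audit", exclusion_reason = "internal_nonpublic")
spec("human subjects review board status", "irb_review_status", "free_text",
     fdaaa_field = "Human Subject Protection Review Board Status",
     requirement = "excluded_from_audit", exclusion_reason = "internal_nonpublic")
spec("responsible party contact information", "responsible_party_contact",
     "composite", fdaaa_field = "Responsible Party Contact Information",
     requirement = "excluded_from_audit", exclusion_reason = "internal_nonpublic")

spec("studies an fda-regulated drug product", "oversight_info/is_fda_regulated_drug",
     "boolean", xsd_typed = TRUE,
     fdaaa_field = "Studies an FDA-regulated Drug Product",
     requirement = "excluded_from_audit", exclusion_reason = "post_2017_addition")
spec("studies an fda-regulated device product",
     "oversight_info/is_fda_regulated_device", "boolean", xsd_typed = TRUE,
     fdaaa_field = "Studies an FDA-regulated Device Product",
     requirement = "excluded_from_audit", exclusion_reason = "post_2017_addition")
spec("device not approved or cleared", "oversight_info/is_unapproved_device",
     "boolean", xsd_typed = TRUE,
     fdaaa_field = "Device or Product Not Approved/Cleared by FDA",
     requirement = "excluded_from_audit", exclusion_reason = "post_2017_addition")

spec("unique protocol identification number", "id_info/org_study_id", "free_text",
     fdaaa_field = "Unique Protocol Identification Number",
     who_field = "Primary Registry and Trial Identifying Number",
     requirement = "excluded_from_audit", exclusion_reason = "administrative_always_present")
spec("record verification date", "verification_date", "date", xsd_typed = TRUE,
     fdaaa_field = "Record Verification Date",
     requirement = "excluded_from_audit", exclusion_reason = "administrative_always_present")

## ---- remaining typed / enumerated elements ---------------------------------

spec("data monitoring committee", "oversight_info/has_dmc", "boolean",
     xsd_typed = TRUE)
spec("gender based", "eligibility/gender_based", "boolean", xsd_typed = TRUE)
spec("expanded access type individual", "expanded_access_type_individual",
     "boolean", xsd_typed = TRUE, applicability = "expanded_access")
spec("expanded access type intermediate", "expanded_access_type_intermediate",
     "boolean", xsd_typed = TRUE, applicability = "expanded_access")
spec("expanded access type treatment", "expanded_access_type_treatment",
     "boolean", xsd_typed = TRUE, applicability = "expanded_access")
spec("number of groups", "number_of_groups", "integer", xsd_typed = TRUE,
     applicability = "observational")

spec("sampling method", "eligibility/sampling_method", "enumerated",
     allowed_dict = "Probability Sample|Non-Probability Sample", xsd_typed = TRUE,
     applicability = "observational")
spec("observational study model", "study_design_info/observational_model",
     "enumerated",
     allowed_dict = "Cohort|Case-Control|Case-Only|Case-Crossover|Ecologic or Community Studies|Family-Based|Other",
     applicability = "observational")
spec("time perspective", "study_design_info/time_perspective", "enumerated",
     allowed_dict = "Retrospective|Prospective|Cross-sectional|Other",
     applicability = "observational")

## ---- principal-investigator and contact elements ---------------------------

spec("overall official", "overall_official", "composite", multiplicity = "multiple",
     who_field = "Contact for Scientific Queries")
spec("overall official name", "overall_official/last_name", "free_text",
     multiplicity = "multiple", parent = "overall official")
spec("overall official role", "overall_official/role", "enumerated",
     allowed_dict = "Study Chair|Study Director|Study Principal Investigator",
     multiplicity = "multiple", xsd_typed = TRUE, parent = "overall official")
spec("overall official affiliation", "overall_official/affiliation", "free_text",
     multiplicity = "multiple", parent = "overall official")

spec("overall contact", "overall_contact", "composite",
     who_field = "Contact for Public Queries")
spec("overall contact name", "overall_contact/last_name", "free_text",
     parent = "overall contact")
spec("overall contact phone", "overall_contact/phone", "free_text",
     parent = "overall contact")
spec("overall contact phone extension", "overall_contact/phone_ext", "free_text",
     parent = "overall contact")
spec("overall contact email", "overall_contact/email", "free_text",
     parent = "overall contact")
spec("overall contact backup", "overall_contact_backup", "composite")
spec("backup contact name", "overall_contact_backup/last_name", "free_text",
     parent = "overall contact backup")
spec("backup contact phone", "overall_contact_backup/phone", "free_text",
     parent = "overall contact backup")
spec("backup contact email", "overall_contact_backup/email", "free_text",
     parent = "overall contact backup")

spec("site contact name", "location/contact/last_name", "free_text",
     multiplicity = "multiple", parent = "facility contact")
spec("site contact phone", "location/contact/phone", "free_text",
     multiplicity = "multiple", parent = "facility contact")
spec("site contact email", "location/contact/email", "free_text",
     multiplicity = "multiple", parent = "facility contact")
spec("site investigator", "location/investigator", "composite",
     multiplicity = "multiple", parent = "facility information")

spec("investigator full name", "responsible_party/investigator_full_name",
     "free_text")
spec("investigator affiliation", "responsible_party/investigator_affiliation",
     "free_text")
spec("investigator title", "responsible_party/investigator_title", "free_text")

## ---- identifiers, descriptive and administrative elements ------------------

spec("nct number", "id_info/nct_id", "free_text")
spec("nct alias", "id_info/nct_alias", "free_text", multiplicity = "multiple")
spec("acronym", "acronym", "free_text")
spec("record source", "source", "free_text")
spec("detailed description", "detailed_description/textblock", "free_text")
spec("keyword", "keyword", "ontology_recommended", multiplicity = "multiple")
# agency class is constrained in practice (NIH / U.S. Fed / Industry / Other) but
# is a sponsor attribute rather than one of the dictionary's sixteen
# enumerated-value fields; it is typed downstream on the record object
spec("agency class", "sponsors/lead_sponsor/agency_class", "free_text",
     xsd_typed = TRUE)
spec("collaborator", "sponsors/collaborator/agency", "free_text",
     multiplicity = "multiple")
spec("collaborator agency class", "sponsors/collaborator/agency_class",
     "free_text", xsd_typed = TRUE, multiplicity = "multiple")
spec("oversight authority", "oversight_info/authority", "free_text",
     multiplicity = "multiple")
spec("study population", "eligibility/study_pop/textblock", "free_text",
     applicability = "observational")
spec("gender description", "eligibility/gender_description", "free_text")
spec("target duration", "target_duration", "free_text",
     applicability = "observational")
spec("biospecimen retention", "biospec_retention", "free_text",
     applicability = "observational")
spec("biospecimen description", "biospec_descr/textblock", "free_text",
     applicability = "observational")
spec("other outcome measure", "other_outcome", "composite",
     multiplicity = "multiple", applicability = IO)
spec("other outcome name", "other_outcome/measure", "free_text",
     multiplicity = "multiple", parent = "other outcome measure")
spec("other outcome time frame", "other_outcome/time_frame", "free_text",
     multiplicity = "multiple", parent = "other outcome measure")
spec("other outcome description", "other_outcome/description", "free_text",
     multiplicity = "multiple", parent = "other outcome measure")
spec("intervention arm group label", "intervention/arm_group_label", "free_text",
     multiplicity = "multiple")
spec("link url", "link/url", "free_text", multiplicity = "multiple")
spec("link description", "link/description", "free_text",
     multiplicity = "multiple")
spec("reference citation", "reference/citation", "free_text",
     multiplicity = "multiple")
spec("reference pmid", "reference/PMID", "free_text", multiplicity = "multiple")
spec("results reference citation", "results_reference/citation", "free_text",
     multiplicity = "multiple")
spec("results reference pmid", "results_reference/PMID", "free_text",
     multiplicity = "multiple")
spec("location country", "location_countries/country", "free_text",
     multiplicity = "multiple")
spec("removed country", "removed_countries/country", "free_text",
     multiplicity = "multiple")
spec("condition mesh term", "condition_browse/mesh_term", "ontology_recommended",
     multiplicity = "multiple")
spec("intervention mesh term", "intervention_browse/mesh_term",
     "ontology_recommended", multiplicity = "multiple")
spec("facility state", "location/facility/address/state", "free_text",
     multiplicity = "multiple", parent = "facility information")
spec("facility zip", "location/facility/address/zip", "free_text",
     multiplicity = "multiple", parent = "facility information")
spec("site investigator name", "location/investigator/last_name", "free_text",
     multiplicity = "multiple", parent = "site investigator")
spec("site investigator role", "location/investigator/role", "free_text",
     multiplicity = "multiple", parent = "site investigator")
spec("study first submitted", "study_first_submitted", "free_text")
spec("study first posted", "study_first_posted", "free_text")
spec("last update submitted", "last_update_submitted", "free_text")
spec("last update posted", "last_update_posted", "free_text")
spec("results first submitted", "results_first_submitted", "free_text")
spec("results first posted", "results_first_posted", "free_text")
spec("disposition first submitted", "disposition_first_submitted", "free_text")
spec("ipd sharing statement", "patient_data/sharing_ipd", "free_text")
spec("ipd description", "patient_data/ipd_description", "free_text")
spec("ipd information type", "patient_data/ipd_info_type", "free_text",
     multiplicity = "multiple")
spec("ipd time frame", "patient_data/ipd_time_frame", "free_text")
spec("ipd access criteria", "patient_data/ipd_access_criteria", "free_text")
spec("ipd url", "patient_data/ipd_url", "free_text")
spec("provided document type", "provided_document_section/provided_document/document_type",
     "free_text", multiplicity = "multiple")
spec("provided document url", "provided_document_section/provided_document/document_url",
     "free_text", multiplicity = "multiple")
spec("provided document date", "provided_document_section/provided_document/document_date",
     "free_text", multiplicity = "multiple")
spec("expanded access nct id", "id_info/expanded_access_nct_id", "free_text",
     applicability = "expanded_access")
spec("clinical results flag", "clinical_results_flag", "free_text")
spec("study docs", "study_docs/study_doc", "composite", multiplicity = "multiple")
spec("study doc id", "study_docs/study_doc/doc_id", "free_text",
     multiplicity = "multiple", parent = "study docs")
spec("study doc type", "study_docs/study_doc/doc_type", "free_text",
     multiplicity = "multiple", parent = "study docs")
spec("study doc url", "study_docs/study_doc/doc_url", "free_text",
     multiplicity = "multiple", parent = "study docs")
spec("study doc comment", "study_docs/study_doc/doc_comment", "free_text",
     multiplicity = "multiple", parent = "study docs")
spec("enrollment type", "enrollment_type", "free_text")
spec("completion date type", "completion_date_type", "free_text")

registry <- bind_rows(rows)

## ---- structural assertions --------------------------------------------------

stopifnot(!anyDuplicated(registry$dictionary_name))
stopifnot(!anyDuplicated(registry$xml_path[registry$xml_path != ""]))
stopifnot(all(registry$parent %in% c("", registry$dictionary_name)))
audited <- registry %>%
  filter(requirement %in% c("always", "conditional"), fdaaa_field != "")
stopifnot(nrow(audited) == 28)
excl <- table(registry$exclusion_reason[registry$exclusion_reason != "none"])
stopifnot(excl[["conditional_unknowable"]] == 5,
          excl[["internal_nonpublic"]] == 3,
          excl[["post_2017_addition"]] == 3,
          excl[["administrative_always_present"]] == 2)
enum <- filter(registry, value_kind == "enumerated")
# Table 4's sixteen enumerated-value fields, nine of them XSD-typed
stopifnot(nrow(enum) == 16, sum(enum$xsd_typed) == 9)
stopifnot(sum(registry$value_kind == "boolean") == 11,
          sum(registry$value_kind == "integer") == 3,
          sum(registry$value_kind == "date") == 4,
          sum(registry$value_kind == "age") == 2)
stopifnot((registry$allowed_dict != "") == (registry$value_kind == "enumerated"))
stopifnot(nrow(registry) == 149)
cat("rows:", nrow(registry), " audited:", nrow(audited),
    " enumerated:", nrow(enum), "\n")

readr::write_tsv(registry, "inst/extdata/field_registry.tsv")
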