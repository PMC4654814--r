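#' Probe roles recognised in a dosage-assay manifest
#'
#' Target probes interrogate one candidate gene each; reference probes sit in
#' loci assumed to carry two copies in every sample and drive intra-sample
#' normalization; ligation controls report ligation success and denaturation
#' controls only yield signal when genomic DNA failed to denature.
#'
#' @export
PROBE_ROLES <- c("target", "reference", "ligation_control", "denaturation_control")

#' The 16 reverse cholesterol transport pathway genes screened by default
#'
#' Scavenger receptor, apolipoproteins, lipases, LCAT, PLTP, LDLR, CETP and
#' ABCA1 -- the gene network moving cholesterol from peripheral tissue back to
#' the liver.
#'
#' @export
RCT_GENES <- c("SRBI", "APOC3", "APOA1", "APOE", "PLTP", "LIPC", "LCAT",
               "APOA4", "LPL", "LIPG", "LDLR", "CETP", "APOA5", "APOB",
               "ABCA1", "APOC2")

# chromosome of each default target probe (single CNV probe per gene)
.RCT_CHROM <- c(SRBI = "12", APOC3 = "11", APOA1 = "11", APOE = "19",
                PLTP = "20", LIPC = "15", LCAT = "16", APOA4 = "11",
                LPL = "8", LIPG = "18", LDLR = "19", CETP = "16",
                APOA5 = "11", APOB = "2", ABCA1 = "9", APOC2 = "19")

#' Build the default probe manifest for the RCT CNV screen
#'
#' Produces a 35-probe manifest: one target probe per RCT gene, sixteen
#' two-copy reference probes (`Ref_1`--`Ref_16`), one ligation-control probe
#' (`Ref_18`) and two denaturation-control probes (`Ref_17`, `Ref_19`).
#' Optionally appends a multicopy-locus target probe (a defensin-like locus
#' whose copy number spans a wide integer range) used by the known-copy
#' quality-control panel.
#'
#' Coordinates are probe anchor positions, 1-based inclusive; they identify
#' the loci but are not used in any computation.
#'
#' @param multicopy if `TRUE`, append a `DEFB103A` target probe so that
#'   [simulate_multicopy_controls()] and anchored cluster calling can be
#'   exercised.
#' @return a `probe_manifest` data frame with columns `probe_id`, `gene`,
#'   `role`, `chrom`, `start`, `end`, `known_copies`.
#' @export
#' @examples
#' m <- rct_manifest()
#' table(m$role)
rct_manifest <- function(multicopy = FALSE) {
  targets <- data.frame(
    probe_id = paste0(RCT_GENES, "_T1"),
    gene = RCT_GENES,
    role = "target",
    chrom = unname(.RCT_CHROM[RCT_GENES]),
    start = 1000000L + 1000L * seq_along(RCT_GENES),
    end   = 1000060L + 1000L * seq_along(RCT_GENES),
    known_copies = NA_integer_,
    stringsAsFactors = FALSE
  )
  refs <- data.frame(
    probe_id = paste0("Ref_", 1:16),
    gene = paste0("REFLOC_", 1:16),
    role = "reference",
    chrom = as.character(rep(1:8, 2)),
    start = 5000000L + 1000L * (1:16),
    end   = 5000060L + 1000L * (1:16),
    known_copies = 2L,
    stringsAsFactors = FALSE
  )
  controls <- data.frame(
    probe_id = c("Ref_17", "Ref_18", "Ref_19"),
    gene = c("DENAT_CTRL_1", "LIG_CTRL_1", "DENAT_CTRL_2"),
    role = c("denaturation_control", "ligation_control", "denaturation_control"),
    chrom = c("3", "5", "7"),
    start = 6000000L + c(1000L, 2000L, 3000L),
    end   = 6000060L + c(1000L, 2000L, 3000L),
    known_copies = NA_integer_,
    stringsAsFactors = FALSE
  )
  m <- rbind(targets, refs, controls)
  if (multicopy) {
    m <- rbind(m, data.frame(
      probe_id = "DEFB103A_T1", gene = "DEFB103A", role = "target",
      chrom = "8", start = 7000000L, end = 7000060L,
      known_copies = NA_integer_, stringsAsFactors = FALSE
    ))
  }
  validate_manifest(m)
}

#' Validate a probe manifest
#'
#' Checks the structural invariants a dosage-assay manifest must satisfy:
#' unique probe ids, recognised roles, at least two reference probes (the
#' minimum for intra-sample normalization), each target probe mapped to
#' exactly one gene, and non-negative `known_copies` where present.
#'
#' @param manifest a data frame with the manifest columns.
#' @return the manifest, classed `probe_manifest`, invisibly usable downstream.
#' @export
validate_manifest <- function(manifest) {
  required <- c("probe_id", "gene", "role", "chrom", "start", "end", "known_copies")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0) {
    stop("manifest error: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(manifest$probe_id)) {
    dup <- unique(manifest$probe_id[duplicated(manifest$probe_id)])
    stop("manifest error: duplicate probe_id: ", paste(dup, collapse = ", "))
  }
  bad_role <- setdiff(unique(manifest$role), PROBE_ROLES)
  if (length(bad_role) > 0) {
    stop("manifest error: unknown role: ", paste(bad_role, collapse = ", "))
  }
  if (sum(manifest$role == "reference") < 2) {
    stop("manifest error: a valid MLPA manifest requires >= 2 reference probes")
  }
  tg <- manifest[manifest$role == "target", ]
  if (anyDuplicated(tg$gene)) {
    stop("manifest error: more than one target probe per gene: ",
         paste(unique(tg$gene[duplicated(tg$gene)]), collapse = ", "))
  }
  kc <- manifest$known_copies
  if (any(!is.na(kc) & kc < 0)) stop("manifest error: known_copies must be >= 0")
  class(manifest) <- c("probe_manifest", "data.frame")
  manifest
}

#' Read a probe manifest from a TSV file
#'
#' Expects a header line `probe_id gene role chrom start end known_copies`
#' (tab-separated). Blank `known_copies` fields are read as missing.
#'
#' @param path path to the manifest TSV.
#' @return validated `probe_manifest` data frame.
#' @export
read_probe_manifest <- function(path) {
  m <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character",
                                        known_copies = "integer"))
  validate_manifest(m)
}

#' Write a probe manifest to a TSV file
#'
#' @param manifest a validated manifest.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# probe ids of a role, in manifest order
probes_of_role <- function(manifest, role) {
  manifest$probe_id[manifest$role %in% role]
}

# named map target probe_id -> gene
target_gene_map <- function(manifest) {
  tg <- manifest[manifest$role == "target", ]
  stats::setNames(tg$gene, tg$probe_id)
}
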