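#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the analysis. Defaults reproduce the
#' protocol the pipeline was designed around: 36-nt single-end reads from a
#' small RNA library built with the Illumina v1.0 adaptors, dual-end 22-nt
#' perfect-match alignment obtained by stripping 14 bases from either end of
#' the tag, 100-200 nt flanking windows for precursor discovery, a 60-150 nt
#' precursor scan narrowed to a final 60-80 nt hairpin, and an MFE acceptance
#' cutoff of -30 kcal/mol.
#'
#' @param adaptor_5p 5' adaptor sequence (ligated upstream of the insert).
#' @param adaptor_3p 3' adaptor sequence (read into when the insert is short).
#' @param read_length fixed read length in nt.
#' @param min_adaptor_overlap minimum exact adaptor overlap (nt) to call an
#'   adaptor end; shorter matches are treated as absent.
#' @param end_query_length length (nt) of the end queries used for alignment.
#' @param strip_length bases stripped from one end to form the opposite-end
#'   query; `read_length - strip_length` must equal `end_query_length`.
#' @param flank_min,flank_max admissible flanking-window half-widths (nt).
#' @param flank_default flank used by the pipeline when scanning candidates.
#' @param precursor_scan_min,precursor_scan_max subwindow lengths (nt)
#'   enumerated during the precursor scan.
#' @param precursor_final_min,precursor_final_max accepted precursor size
#'   range (nt).
#' @param mfe_cutoff maximum (i.e. least negative) free energy, kcal/mol, for
#'   an accepted precursor.
#' @param min_mature_pairs minimum number of mature nucleotides that must be
#'   paired to the opposite arm.
#' @param mature_pair_mode `"total"` counts all paired mature nucleotides;
#'   `"contiguous"` counts the run of consecutively paired nucleotides from
#'   the mature 5' end.
#' @param max_internal_loop maximum internal-loop side length (nt).
#' @param max_bulge_asymmetry maximum side-length difference (nt) of any
#'   interior loop.
#' @param multi_locus_report_cap maximum number of loci listed for a
#'   multi-mapping tag.
#' @param homology_max_edit maximum edit distance for a full-length homology
#'   match against known miRNAs.
#' @param tag_id_prefix prefix used when assigning tag identifiers.
#' @param rng_seed integer seed for any randomised step.
#' @return a list of class `srna_config`.
#' @examples
#' cfg <- run_config()
#' cfg$mfe_cutoff
#' @export
run_config <- function(adaptor_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                       adaptor_3p = "TCGTATGCCGTCTTCTGCTTGT",
                       read_length = 36L,
                       min_adaptor_overlap = 6L,
                       end_query_length = 22L,
                       strip_length = 14L,
                       flank_min = 100L,
                       flank_max = 200L,
                       flank_default = 150L,
                       precursor_scan_min = 60L,
                       precursor_scan_max = 150L,
                       precursor_final_min = 60L,
                       precursor_final_max = 80L,
                       mfe_cutoff = -30,
                       min_mature_pairs = 16L,
                       mature_pair_mode = c("total", "contiguous"),
                       max_internal_loop = 10L,
                       max_bulge_asymmetry = 4L,
                       multi_locus_report_cap = 10L,
                       homology_max_edit = 2L,
                       tag_id_prefix = "tag",
                       rng_seed = 1L) {
  mature_pair_mode <- match.arg(mature_pair_mode)
  assert_dna(c(adaptor_5p, adaptor_3p), allow_n = FALSE, what = "adaptor")
  abort_if(read_length - strip_length != end_query_length,
           "read_length - strip_length (%d) must equal end_query_length (%d)",
           read_length - strip_length, end_query_length)
  abort_if(flank_min > flank_max, "flank_min exceeds flank_max")
  abort_if(flank_default < flank_min || flank_default > flank_max,
           "flank_default outside [flank_min, flank_max]")
  abort_if(precursor_scan_min > precursor_scan_max, "precursor scan range empty")
  abort_if(precursor_final_min > precursor_final_max, "precursor final range empty")
  cfg <- list(
    adaptor_5p = toupper(adaptor_5p), adaptor_3p = toupper(adaptor_3p),
    read_length = as.integer(read_length),
    min_adaptor_overlap = as.integer(min_adaptor_overlap),
    end_query_length = as.integer(end_query_length),
    strip_length = as.integer(strip_length),
    flank_min = as.integer(flank_min), flank_max = as.integer(flank_max),
    flank_default = as.integer(flank_default),
    precursor_scan_min = as.integer(precursor_scan_min),
    precursor_scan_max = as.integer(precursor_scan_max),
    precursor_final_min = as.integer(precursor_final_min),
    precursor_final_max = as.integer(precursor_final_max),
    mfe_cutoff = as.numeric(mfe_cutoff),
    min_mature_pairs = as.integer(min_mature_pairs),
    mature_pair_mode = mature_pair_mode,
    max_internal_loop = as.integer(max_internal_loop),
    max_bulge_asymmetry = as.integer(max_bulge_asymmetry),
    multi_locus_report_cap = as.integer(multi_locus_report_cap),
    homology_max_edit = as.integer(homology_max_edit),
    tag_id_prefix = tag_id_prefix,
    rng_seed = as.integer(rng_seed)
  )
  structure(cfg, class = "srna_config")
}

#' @export
print.srna_config <- function(x, ...) {
  cat("<srna_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = " ")))
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @return `read_config()` returns an `srna_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_config
#' @param config an `srna_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
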