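#' Coiled-coil pair libraries
#'
#' A CC pair is one building block of the design toolkit: the two peptide
#' sequences forming a dimer, their mutual orientation, and an orthogonality
#' group. Peptides from different groups are assumed not to cross-pair;
#' peptides sharing a group (e.g. an SN module and its SH variant with
#' enhanced helical propensity) do cross-talk and must not be reused within
#' one folding scope.
#'
#' @name cc_library
NULL

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_aa <- function(seq) {
  bad <- setdiff(strsplit(seq, "")[[1]], .aa_alphabet)
  if (length(bad)) stop("non-amino-acid character(s): ", paste(bad, collapse = ""))
  invisible(TRUE)
}

#' Load a CC pair library from a delimited table
#'
#' Expected tab-separated columns: `name`, `seq_a`, `seq_b`, `orientation`
#' (`parallel` or `antiparallel`), `group`, `variant`.
#'
#' @param path Path to a TSV file.
#' @return Data frame of class `cc_library` with an added logical
#'   `homodimer` column (`seq_a == seq_b`).
#' @export
load_cc_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "seq_a", "seq_b", "orientation", "group", "variant")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("malformed library: missing column(s) ",
                            paste(missing, collapse = ", "))
  if (any(!nzchar(df$seq_a)) || any(!nzchar(df$seq_b))) {
    stop("malformed row: empty sequence")
  }
  invisible(lapply(c(df$seq_a, df$seq_b), .check_aa))
  if (!all(df$orientation %in% c("parallel", "antiparallel"))) {
    stop("orientation must be 'parallel' or 'antiparallel'")
  }
  df$homodimer <- df$seq_a == df$seq_b
  class(df) <- c("cc_library", "data.frame")
  df
}

#' @rdname load_cc_library
#' @param library A `cc_library` data frame.
#' @export
write_cc_library <- function(library, path) {
  cols <- c("name", "seq_a", "seq_b", "orientation", "group", "variant")
  utils::write.table(library[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Packaged synthetic CC pair library
#'
#' A fully synthetic stand-in toolkit shipped with the package (see
#' `inst/extdata/cc_library_synthetic.tsv`). The peptides are idealised
#' 32-residue four-heptad designs (Ile/Asn core with Glu/Lys electrostatic
#' specificity; SH variants carry additional Lys/Glu pairs at b/c positions,
#' emulating helicity-enhancing salt bridges). The pair names follow the
#' published CCPO toolkit nomenclature so that designs read naturally, but
#' the sequences themselves are synthetic fixtures, not the experimentally
#' characterised peptides.
#'
#' @return A `cc_library` data frame.
#' @export
cc_fixture_library <- function() {
  path <- system.file("extdata", "cc_library_synthetic.tsv",
                      package = "ccporigami")
  if (!nzchar(path)) {      # package sources not installed (e.g. dev tree)
    path <- file.path("inst", "extdata", "cc_library_synthetic.tsv")
  }
  load_cc_library(path)
}

#' Generate the synthetic CC library table
#'
#' Deterministically regenerates the packaged fixture library. Heterodimeric
#' pairs differ in the register of the buried Asn residue and in their
#' polar-position pattern, giving each orthogonality group a distinct
#' sequence signature.
#'
#' @param path Optional path; when given the table is written there as TSV.
#' @return The `cc_library` data frame (invisibly when `path` is given).
#' @export
synthetic_cc_library <- function(path = NULL) {
  hept <- function(a, b, c, e, g, f = "Q") paste0(a, b, c, "L", e, f, g)
  four <- function(asn, b, c, e, g, f = "Q") {
    paste(vapply(1:4, function(i) {
      hept(if (i == asn) "N" else "I", b, c, e, g, f)
    }, character(1)), collapse = "")
  }
  cap <- function(core) paste0("SP", core, "GY")
  rows <- list()
  add <- function(name, a, b, ori, group, variant) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, seq_a = a, seq_b = b, orientation = ori,
      group = group, variant = variant, stringsAsFactors = FALSE)
  }
  # six parallel heterodimeric SN pairs: acidic partner + basic partner,
  # Asn register cycles 1..4, f position alternates Q/S for extra signatures
  regs <- c(1, 2, 3, 4, 2, 3)
  fpos <- c("Q", "Q", "Q", "S", "S", "T")
  for (k in seq_len(6)) {
    nm <- sprintf("P%dSN:P%dSN", 2 * k - 1, 2 * k)
    add(nm,
        cap(four(regs[k], "A", "A", "E", "E", fpos[k])),
        cap(four(regs[k], "A", "A", "K", "K", fpos[k])),
        "parallel", sprintf("pg%d", k), "SN")
  }
  # SH variants of pairs 3..6 (same orthogonality groups as their SN parents)
  for (k in 3:6) {
    nm <- sprintf("P%dSH:P%dSH", 2 * k - 1, 2 * k)
    add(nm,
        cap(four(regs[k], "K", "E", "E", "E", fpos[k])),
        cap(four(regs[k], "K", "E", "K", "K", fpos[k])),
        "parallel", sprintf("pg%d", k), "SH")
  }
  # antiparallel homodimers
  aph <- cap("IAALEQKIAALKQEIAALEQKIAALKQE")
  add("APHSN:APHSN", aph, aph, "antiparallel", "aph", "SN")
  bcr <- cap("IAALESKIAALKSEIAALESKIAALKSE")
  add("BCR:BCR", bcr, bcr, "antiparallel", "bcr", "SN")
  bcrsh <- cap("IKELESKIKELKSEIKELESKIKELKSE")
  add("BCRSH:BCRSH", bcrsh, bcrsh, "antiparallel", "bcr", "SH")
  # parallel homodimer
  gcn <- cap("VAALEQKVAALEQKVAALEQKVAALEQK")
  add("GCNSN:GCNSN", gcn, gcn, "parallel", "gcn", "SN")

  df <- do.call(rbind, rows)
  df$homodimer <- df$seq_a == df$seq_b
  class(df) <- c("cc_library", "data.frame")
  if (!is.null(path)) {
    write_cc_library(df, path)
    return(invisible(df))
  }
  df
}
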