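#' Sequence assembly, molecular weight and TEV cleavage
#'
#' Turns a topology plus segment assignment into one annotated amino-acid
#' sequence per chain: segment - linker - segment - ..., with optional
#' terminal tags and protease cleavage sites at annotated junctions.
#'
#' @name assembly
NULL

#' Default linker and tag set
#'
#' Flexible Gly/Ser/Pro linkers and standard affinity tags used when the
#' caller does not provide construct-specific ones. `tev` is the linker
#' variant carrying a TEV protease recognition site (cleaved after the Gln
#' of `ENLYFQ|S`).
#'
#' @return Named list with `linker`, `tev_linker`, `tev_site`, `his_tag`,
#'   `strep_tag`.
#' @export
default_construct_parts <- function() {
  list(linker = "GSGPG",
       tev_site = "ENLYFQS",
       tev_linker_pre = "GS", tev_linker_post = "GS",
       his_tag = "MHHHHHHGS",
       strep_tag = "WSHPQFEKGS")
}

#' Assemble annotated chain sequences
#'
#' @param assignment A `segment_assignment` from [assign_segments()].
#' @param topology The matching `chain_topology`.
#' @param linker Inter-segment linker peptide (default `"GSGPG"`); an empty
#'   string gives direct fusion.
#' @param n_tag,c_tag Optional terminal tag peptides applied to every chain.
#' @param parts Construct part set, see [default_construct_parts()].
#' @return List of `annotated_sequence` objects (one per chain): each a list
#'   with `chain_id`, `residues`, and `annotations` (data frame with
#'   `start`, `end`, `type` in segment/linker/tag/cleavage, `label`).
#'   Junctions listed in `topology$cleavage_sites` receive a
#'   linker-embedded TEV recognition site.
#' @export
assemble_sequence <- function(assignment, topology, linker = "GSGPG",
                              n_tag = "", c_tag = "",
                              parts = default_construct_parts()) {
  if (is.null(linker)) stop("missing linker definition")
  ch <- chain_of(topology)
  seqs_by_segment <- assignment$table$sequence[
    match(seq_len(n_segments(topology)), assignment$table$segment)]
  if (anyNA(seqs_by_segment)) stop("assignment does not cover every segment")
  cleav <- topology$cleavage_sites

  lapply(unique(ch), function(c_id) {
    segs <- which(ch == c_id)
    res <- ""
    ann <- data.frame(start = integer(0), end = integer(0),
                      type = character(0), label = character(0),
                      stringsAsFactors = FALSE)
    push <- function(piece, type, label) {
      if (!nzchar(piece)) return(invisible(NULL))
      s <- nchar(res) + 1L
      res <<- paste0(res, piece)
      ann[nrow(ann) + 1L, ] <<- list(s, nchar(res), type, label)
      invisible(NULL)
    }
    push(n_tag, "tag", "n_tag")
    for (k in seq_along(segs)) {
      seg <- segs[k]
      lab <- assignment$table$pair[match(seg, assignment$table$segment)]
      push(seqs_by_segment[seg], "segment",
           sprintf("seg%d|%s", seg, lab))
      if (k < length(segs)) {
        pos_in_chain <- k
        has_site <- !is.null(cleav) &&
          any(cleav$chain == c_id & cleav$after_segment == pos_in_chain)
        if (has_site) {
          push(parts$tev_linker_pre, "linker", "linker")
          push(parts$tev_site, "cleavage", "tev_site")
          push(parts$tev_linker_post, "linker", "linker")
        } else {
          push(linker, "linker", "linker")
        }
      }
    }
    push(c_tag, "tag", "c_tag")
    structure(list(chain_id = sprintf("chain%d", c_id),
                   residues = res, annotations = ann),
              class = "annotated_sequence")
  })
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat(sprintf("annotated_sequence %s: %d aa, %d annotation intervals\n",
              x$chain_id, nchar(x$residues), nrow(x$annotations)))
  invisible(x)
}

# Average and monoisotopic residue masses (Da)
.aa_mass <- list(
  average = c(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326),
  monoisotopic = c(
    A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
    E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
    L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
    S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
)
.water_mass <- c(average = 18.0153, monoisotopic = 18.010565)

#' Theoretical molecular weight of a peptide
#'
#' Sum of residue masses plus one water, in kDa. Average isotopic masses by
#' default (matching the precision with which theoretical masses of designed
#' proteins are usually quoted); monoisotopic masses optionally.
#'
#' @param seq Amino-acid string (standard 20-letter alphabet) or an
#'   `annotated_sequence`.
#' @param monoisotopic Use monoisotopic masses.
#' @return Mass in kDa.
#' @examples
#' molecular_weight("G")   # 0.0750672 kDa
#' @export
molecular_weight <- function(seq, monoisotopic = FALSE) {
  if (inherits(seq, "annotated_sequence")) seq <- seq$residues
  tab <- if (monoisotopic) .aa_mass$monoisotopic else .aa_mass$average
  water <- .water_mass[[if (monoisotopic) "monoisotopic" else "average"]]
  chars <- strsplit(seq, "")[[1]]
  m <- tab[chars]
  if (anyNA(m)) stop("unknown residue symbol: ",
                     paste(unique(chars[is.na(m)]), collapse = ""))
  (sum(m) + water) / 1000
}

#' Cleave an annotated sequence with TEV protease in silico
#'
#' Cuts between the Gln and the following residue of each annotated
#' `ENLYFQ(G|S)` site. Fragments inherit re-derived annotation intervals.
#' A sequence without cleavage annotations is returned unchanged (as a
#' one-element list).
#'
#' @param seq An `annotated_sequence`.
#' @return List of `annotated_sequence` fragments, N- to C-terminal.
#' @export
tev_cleave <- function(seq) {
  ann <- seq$annotations
  sites <- ann[ann$type == "cleavage", , drop = FALSE]
  if (nrow(sites) == 0) return(list(seq))
  cuts <- integer(0)
  for (r in seq_len(nrow(sites))) {
    s <- sites$start[r]
    window <- substr(seq$residues, s, s + 6)
    if (!grepl("^ENLYFQ[GS]", window)) {
      stop("cleavage annotation at ", s,
           " does not sit on an ENLYFQ(G|S) recognition sequence")
    }
    cuts <- c(cuts, s + 5L)   # cut after the Gln
  }
  cuts <- sort(unique(cuts))
  bounds <- cbind(c(1L, cuts + 1L), c(cuts, nchar(seq$residues)))
  lapply(seq_len(nrow(bounds)), function(f) {
    a <- bounds[f, 1]; b <- bounds[f, 2]
    keep <- ann[ann$end >= a & ann$start <= b, , drop = FALSE]
    keep$start <- pmax(keep$start, a) - a + 1L
    keep$end <- pmin(keep$end, b) - a + 1L
    rownames(keep) <- NULL
    structure(list(chain_id = sprintf("%s_frag%d", seq$chain_id, f),
                   residues = substr(seq$residues, a, b),
                   annotations = keep),
              class = "annotated_sequence")
  })
}

#' Extract annotated segments from an assembled sequence
#'
#' @param seq An `annotated_sequence`.
#' @param type Annotation type to extract (default `"segment"`).
#' @return Named character vector of subsequences.
#' @export
extract_intervals <- function(seq, type = "segment") {
  ann <- seq$annotations[seq$annotations$type == type, , drop = FALSE]
  stats::setNames(substring(seq$residues, ann$start, ann$end), ann$label)
}

#' Write chains to a FASTA file
#'
#' @param seqs List of `annotated_sequence` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chains_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    nm <- names(seqs); ss <- seqs
  } else {
    nm <- vapply(seqs, function(s) s$chain_id, character(1))
    ss <- vapply(seqs, function(s) s$residues, character(1))
  }
  seqinr::write.fasta(as.list(ss), names = nm, file.out = path,
                      as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences (upper case).
#' @export
read_fasta_sequences <- function(path) {
  x <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  stats::setNames(toupper(vapply(x, function(s) as.character(s)[1],
                                 character(1))),
                  names(x))
}
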