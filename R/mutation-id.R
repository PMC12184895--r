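#' Canonical mitochondrial mutation identifiers
#'
#' Mutations are named \code{"MT_<position>_<ref>-<alt>"} with a 1-based
#' position on the 16,569-bp human mitochondrial reference and single-base
#' reference and alternate alleles, e.g. \code{"MT_16389_G-A"}.
#'
#' @param id character vector of identifiers to parse.
#' @return \code{parseMutationId}: a \code{data.frame} with columns
#'   \code{position} (integer), \code{ref} and \code{alt} (character), one
#'   row per input id, row names preserved from \code{id}.
#' @examples
#' parseMutationId("MT_16389_G-A")
#' makeMutationId(3243, "A", "G")
#' @export
parseMutationId <- function(id) {
    stopifnot(is.character(id))
    m <- regmatches(id, regexec("^MT_([0-9]+)_([ACGT])-([ACGT])$", id))
    bad <- which(lengths(m) != 4L)
    if (length(bad))
        stop("unparseable mutation identifier at row ", bad[1L], ": '",
             id[bad[1L]], "'")
    pos <- as.integer(vapply(m, `[`, "", 2L))
    ref <- vapply(m, `[`, "", 3L)
    alt <- vapply(m, `[`, "", 4L)
    if (any(pos < 1L | pos > MT_GENOME_LENGTH))
        stop("mutation position outside 1..", MT_GENOME_LENGTH)
    if (any(ref == alt))
        stop("ref and alt allele must differ")
    data.frame(position = pos, ref = ref, alt = alt, row.names = id)
}

#' @rdname parseMutationId
#' @param position integer vector of 1-based MT positions.
#' @param ref,alt single-base reference/alternate alleles (A/C/G/T).
#' @return \code{makeMutationId}: the canonical identifier string(s).
#' @export
makeMutationId <- function(position, ref, alt) {
    position <- as.integer(position)
    stopifnot(all(position >= 1L), all(position <= MT_GENOME_LENGTH),
              all(ref %in% c("A", "C", "G", "T")),
              all(alt %in% c("A", "C", "G", "T")), all(ref != alt))
    sprintf("MT_%d_%s-%s", position, ref, alt)
}
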