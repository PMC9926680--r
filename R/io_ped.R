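#' Read pedigree trios from a PED file
#'
#' Parses the 6-column PED dialect (family, individual, father, mother, sex,
#' phenotype; whitespace separated, `"0"` marking an unavailable parent) and
#' assembles one trio skeleton per individual. Singletons (both parents `"0"`)
#' are allowed; an absent parent is recorded as `NA`, never imputed.
#'
#' @param path PED file.
#' @return A data.frame with columns `family_id`, `proband_id`, `father_id`,
#'   `mother_id` (`NA` when unavailable), `sex` (`"M"`, `"F"`, or `NA`) and
#'   `affected` (logical, from the phenotype column).
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("no such PED: ", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 6) stop("PED requires 6 columns, found ", ncol(tab))
  names(tab)[1:6] <- c("family_id", "proband_id", "father_id", "mother_id",
                       "sex", "phenotype")
  none <- function(x) ifelse(x == "0", NA_character_, x)
  ped <- data.frame(
    family_id = tab$family_id, proband_id = tab$proband_id,
    father_id = none(tab$father_id), mother_id = none(tab$mother_id),
    sex = c("1" = "M", "2" = "F")[tab$sex],
    affected = tab$phenotype == "2",
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ped$proband_id))
    stop("duplicate individual id in PED")
  ## cycle check on the parentage graph (an individual can never be its own
  ## ancestor)
  parents <- function(id) {
    r <- ped[ped$proband_id == id, ]
    if (!nrow(r)) return(character(0))
    stats::na.omit(c(r$father_id, r$mother_id))
  }
  for (id in ped$proband_id) {
    seen <- character(0)
    frontier <- parents(id)
    while (length(frontier)) {
      if (id %in% frontier)
        stop("cyclic parentage involving individual '", id, "'")
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      frontier <- unique(unlist(lapply(frontier, parents)))
    }
  }
  ped
}
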