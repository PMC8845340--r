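#' Construct a pedigree
#'
#' @param id character vector of individual identifiers (unique).
#' @param sire,dam character vectors of parent identifiers; \code{NA} (or
#'   \code{"0"}) for unknown. A parent identifier that has no record of its
#'   own is kept (it simply cannot contribute genotypes).
#' @param sex character vector in \code{c("male", "female", "unknown")}.
#' @return An object of class \code{"pedigree"}: a data.frame with columns
#'   \code{id}, \code{sire}, \code{dam}, \code{sex}.
#' @export
pedigree <- function(id, sire, dam, sex = NULL) {
  id <- as.character(id)
  sire <- as.character(sire); dam <- as.character(dam)
  sire[sire %in% c("0", "")] <- NA
  dam[dam %in% c("0", "")] <- NA
  .stop_if(anyDuplicated(id) > 0, "duplicate individual ids in pedigree")
  if (is.null(sex)) sex <- rep("unknown", length(id))
  sex <- as.character(sex)
  .stop_if(!all(sex %in% c("male", "female", "unknown")),
           "sex must be 'male', 'female' or 'unknown'")
  ped <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                    stringsAsFactors = FALSE)
  .check_no_cycles(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# topological elimination: repeatedly remove individuals whose (known,
# recorded) parents have all been removed; leftovers imply a cycle
.check_no_cycles <- function(ped) {
  parent_of <- function(p) ifelse(!is.na(p) & p %in% ped$id, p, NA)
  s <- parent_of(ped$sire); d <- parent_of(ped$dam)
  done <- rep(FALSE, nrow(ped))
  repeat {
    free <- !done & (is.na(s) | s %in% ped$id[done]) &
      (is.na(d) | d %in% ped$id[done])
    if (!any(free)) break
    done[free] <- TRUE
    if (all(done)) return(invisible(TRUE))
  }
  stop("pedigree contains a cycle (an individual is its own ancestor)")
}

#' Read a PLINK 6-column FAM file
#'
#' Columns: family id, individual id, sire, dam, sex (1 = male, 2 = female,
#' other = unknown), phenotype. Parent code 0 means unknown.
#'
#' @param fam_source path to the FAM file.
#' @return A \code{\link{pedigree}}.
#' @export
read_pedigree <- function(fam_source) {
  x <- utils::read.table(fam_source, header = FALSE,
                         colClasses = "character")
  .stop_if(ncol(x) < 6, "FAM file must have 6 columns")
  sex <- c(`1` = "male", `2` = "female")[x[[5]]]
  sex[is.na(sex)] <- "unknown"
  ped <- pedigree(x[[2]], x[[3]], x[[4]], sex)
  unknown_ref <- setdiff(c(ped$sire, ped$dam), c(NA, ped$id))
  if (length(unknown_ref) > 0) {
    warning(length(unknown_ref),
            " referenced parent id(s) have no pedigree record; ",
            "treated as present but ungenotyped")
  }
  ped
}

#' Write a pedigree as a PLINK FAM file
#'
#' @param ped a \code{\link{pedigree}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  utils::write.table(
    data.frame("FAM", ped$id,
               ifelse(is.na(ped$sire), "0", ped$sire),
               ifelse(is.na(ped$dam), "0", ped$dam),
               sex_code, "-9"),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Find trios (offspring with both parents genotyped)
#'
#' @param ped a \code{\link{pedigree}}.
#' @param sample_ids identifiers of genotyped samples.
#' @return data.frame with columns \code{offspring}, \code{sire}, \code{dam}.
#' @export
find_trios <- function(ped, sample_ids) {
  keep <- ped$id %in% sample_ids &
    !is.na(ped$sire) & ped$sire %in% sample_ids &
    !is.na(ped$dam) & ped$dam %in% sample_ids
  data.frame(offspring = ped$id[keep], sire = ped$sire[keep],
             dam = ped$dam[keep], stringsAsFactors = FALSE)
}

#' Find duos (offspring with exactly one parent genotyped)
#'
#' @inheritParams find_trios
#' @return data.frame with columns \code{offspring}, \code{parent},
#'   \code{parent_role} ("sire" or "dam").
#' @export
find_duos <- function(ped, sample_ids) {
  s_in <- !is.na(ped$sire) & ped$sire %in% sample_ids
  d_in <- !is.na(ped$dam) & ped$dam %in% sample_ids
  keep <- ped$id %in% sample_ids & xor(s_in, d_in)
  data.frame(offspring = ped$id[keep],
             parent = ifelse(s_in[keep], ped$sire[keep], ped$dam[keep]),
             parent_role = ifelse(s_in[keep], "sire", "dam"),
             stringsAsFactors = FALSE)
}

# all genotyped parent-offspring pairs (trios contribute two pairs)
parent_offspring_pairs <- function(ped, sample_ids) {
  s_in <- ped$id %in% sample_ids & !is.na(ped$sire) &
    ped$sire %in% sample_ids
  d_in <- ped$id %in% sample_ids & !is.na(ped$dam) &
    ped$dam %in% sample_ids
  rbind(
    data.frame(offspring = ped$id[s_in], parent = ped$sire[s_in],
               parent_role = "sire", stringsAsFactors = FALSE),
    data.frame(offspring = ped$id[d_in], parent = ped$dam[d_in],
               parent_role = "dam", stringsAsFactors = FALSE))
}
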