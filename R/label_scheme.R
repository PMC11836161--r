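# Fixed numeric coding of the 14 spinal structures. The literature never
# publishes a numeric convention, so this table is the package-wide one;
# it is serialized as a JSON sidecar next to every mask the CLI writes.
.scheme <- data.frame(
  code = 1:14,
  name = c("corpus", "arcus", "spinous_process",
           "articular_inferior_left", "articular_inferior_right",
           "articular_superior_left", "articular_superior_right",
           "costal_process_left", "costal_process_right",
           "endplate", "ivd", "spinal_canal", "spinal_cord", "sacrum"),
  group = c(rep("vertebra", 9), "endplate", "ivd", "canal", "cord", "sacrum"),
  stringsAsFactors = FALSE
)

# Instance identifiers: vertebrae are counted 1..N from top to bottom;
# disc and endplate instances are derived from the owning vertebra id and
# offset into disjoint blocks so the three kinds never collide in one file.
.ivd_id_offset <- 100L
.endplate_id_offset <- 200L

#' The 14-structure semantic scheme
#'
#' Per-voxel codes for the ten vertebral substructures (vertebral body,
#' arch, spinous process, left/right inferior and superior articular
#' processes, left/right costal/transverse processes, endplate) plus the
#' intervertebral disc, spinal canal, spinal cord and sacrum. Code 0 is
#' reserved for background.
#'
#' @return A data.frame with columns `code`, `name`, `group`.
#' @export
semantic_scheme <- function() .scheme

#' @rdname semantic_scheme
#' @param name Structure name(s) from the scheme.
#' @export
scheme_code <- function(name) {
  i <- match(name, .scheme$name)
  if (anyNA(i)) stop("unknown structure name: ",
                     paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  .scheme$code[i]
}

#' Anatomic group of a semantic code
#'
#' Maps each of the 14 structure codes to its anatomic group. All ten
#' vertebral substructure codes except the endplate map to `"vertebra"`;
#' the endplate keeps its own group because instances and several
#' evaluations treat it separately. Background (0) maps to
#' `"background"`.
#'
#' @param code Integer vector of semantic codes.
#' @return Character vector of group names.
#' @export
anatomic_group <- function(code) {
  out <- character(length(code))
  out[code == 0] <- "background"
  known <- code %in% .scheme$code
  out[known & code != 0] <- .scheme$group[match(code[known & code != 0],
                                                .scheme$code)]
  if (any(!known & code != 0))
    stop("unknown semantic code(s): ",
         paste(unique(code[!known & code != 0]), collapse = ", "),
         call. = FALSE)
  out
}

#' @rdname anatomic_group
#' @param group Group name (`"vertebra"`, `"ivd"`, ...).
#' @export
codes_in_group <- function(group) .scheme$code[.scheme$group %in% group]

#' Instance-identifier convention
#'
#' Vertebra instances use ids 1..99, counted from top to bottom. A disc
#' or endplate instance carries the id of its owning vertebra (the
#' nearest vertebra above) offset into a disjoint block: disc ids are
#' `100 + v`, endplate ids `200 + v`.
#'
#' @param v Vertebra id(s), in 1..99.
#' @return The derived instance id(s).
#' @export
ivd_instance_id <- function(v) {
  stopifnot(all(v >= 1 & v < .ivd_id_offset))
  as.integer(.ivd_id_offset + v)
}

#' @rdname ivd_instance_id
#' @export
endplate_instance_id <- function(v) {
  stopifnot(all(v >= 1 & v < .ivd_id_offset))
  as.integer(.endplate_id_offset + v)
}

#' @rdname ivd_instance_id
#' @param id Instance id(s).
#' @export
instance_kind <- function(id) {
  out <- rep(NA_character_, length(id))
  out[id == 0] <- "background"
  out[id >= 1 & id < .ivd_id_offset] <- "vertebra"
  out[id >= .ivd_id_offset & id < .endplate_id_offset] <- "ivd"
  out[id >= .endplate_id_offset & id < 300] <- "endplate"
  if (anyNA(out))
    stop("instance id(s) outside known ranges: ",
         paste(unique(id[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' @rdname ivd_instance_id
#' @export
owning_vertebra <- function(id) {
  kind <- instance_kind(id)
  off <- c(background = NA_integer_, vertebra = 0L,
           ivd = .ivd_id_offset, endplate = .endplate_id_offset)
  as.integer(id - off[kind])
}

#' Write the label-scheme sidecar
#'
#' Serializes the code/name/group table (and the instance id convention)
#' as JSON next to a mask so downstream consumers need not guess the
#' numeric coding.
#'
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_scheme_sidecar <- function(path) {
  jsonlite::write_json(
    list(semantic_codes = .scheme,
         instance_ids = list(vertebra = "1..99 top to bottom",
                             ivd = "100 + owning vertebra id",
                             endplate = "200 + owning vertebra id")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.validate_semantic_codes <- function(data) {
  vals <- unique(as.integer(data))
  bad <- setdiff(vals, c(0L, .scheme$code))
  if (length(bad))
    stop("semantic mask contains codes outside the 14-structure scheme: ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
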