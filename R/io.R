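# File formats and run configuration: VOC-dialect XML annotations and the
# nested YAML run configuration with unknown-key rejection.

LABEL_NAMES <- paste0("tomato", 1:6)

#' Write a scene's annotation as VOC-dialect XML
#'
#' Boxes are stored with 1-based inclusive integer corners per the VOC
#' convention; the package's continuous 0-based corner-form is converted on
#' write and recovered on read, so integer boxes round-trip exactly.
#'
#' @param scene An `rgbd_scene` (or any list with `boxes`, `labels`,
#'   `width`, `height`).
#' @param path Output XML path.
#' @param filename Image filename recorded in the annotation.
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(scene, path, filename = "image.png") {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(scene$width))
  xml2::xml_add_child(size, "height", as.character(scene$height))
  xml2::xml_add_child(size, "depth", "3")
  boxes <- rbind(scene$boxes)
  for (i in seq_len(nrow(boxes))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", LABEL_NAMES[scene$labels[i]])
    xml2::xml_add_child(ob, "difficult", "0")
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(round(boxes[i, 1]) + 1L))
    xml2::xml_add_child(bb, "ymin", as.character(round(boxes[i, 2]) + 1L))
    xml2::xml_add_child(bb, "xmax", as.character(round(boxes[i, 3])))
    xml2::xml_add_child(bb, "ymax", as.character(round(boxes[i, 4])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a VOC-dialect XML annotation
#'
#' @param path XML file path.
#' @return List with `boxes` (N x 4 continuous 0-based corner-form),
#'   `labels` (integer 1-6), `width`, `height`.
#' @export
read_voc_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("failed to parse VOC annotation '", path, "': ",
         conditionMessage(e)))
  objs <- xml2::xml_find_all(doc, ".//object")
  get_num <- function(node, tag)
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, tag)))
  boxes <- matrix(numeric(0), 0L, 4L)
  labels <- integer(0)
  for (ob in objs) {
    name <- xml2::xml_text(xml2::xml_find_first(ob, "name"))
    cls <- match(name, LABEL_NAMES)
    if (is.na(cls)) stop("unknown object label '", name, "' in ", path)
    bb <- xml2::xml_find_first(ob, "bndbox")
    boxes <- rbind(boxes, c(get_num(bb, "xmin") - 1, get_num(bb, "ymin") - 1,
                            get_num(bb, "xmax"), get_num(bb, "ymax")))
    labels <- c(labels, cls)
  }
  colnames(boxes) <- c("x_min", "y_min", "x_max", "y_max")
  list(boxes = boxes, labels = labels,
       width = as.numeric(xml2::xml_text(
         xml2::xml_find_first(doc, ".//size/width"))),
       height = as.numeric(xml2::xml_text(
         xml2::xml_find_first(doc, ".//size/height"))))
}

#' Default run configuration
#'
#' Nested defaults for every stage. Training defaults mirror common practice
#' for this detector family (batch size 8, learning rate 1e-3, Adam,
#' evaluation every 500 iterations); desk-scale runs override `iterations`,
#' `batch_size` and `network$width_multiplier` downwards.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    anchors = list(image_size = 300L),
    match = list(iou_threshold = 0.5),
    nms = list(iou_threshold = 0.45, top_k = 200L),
    augment = list(expand_max_ratio = 4, mirror_prob = 0.5,
                   crop_min_ious = c(0.1, 0.3, 0.5, 0.7, 0.9),
                   rgb_means = NULL, depth_mean = NULL, size = 300L),
    network = list(width_multiplier = 1, use_inception_extras = FALSE),
    loss = list(neg_pos_ratio = 3, alpha = 1),
    eval = list(iou_threshold = 0.5, interpolation = "all",
                conf_threshold = 0.05),
    hrgan = list(n_blocks = 4L, channels = 8L, image_size = 64L,
                 lr = 2e-3, batch_size = 4L),
    training = list(iterations = 500L, batch_size = 8L,
                    learning_rate = 1e-3, optimizer = "adam",
                    eval_every = 500L)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown config key: ", paste0(path, nm))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("config key ", paste0(path, nm), " must be a mapping")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a YAML run configuration
#'
#' Reads a YAML file, rejects unknown keys, and merges over
#' [default_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return The fully-resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  cfg
}
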