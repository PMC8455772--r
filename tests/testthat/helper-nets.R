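# tiny configs and constant-output networks used across test files

tiny_reg_config <- function(head_dim = 2, h = 16, w = 16) {
  backbone_config(c(2, 2), c(4, 6), "regression", head_dim,
                  input_h = h, input_w = w)
}

tiny_cls_config <- function(h = 16, w = 16) {
  backbone_config(c(2, 2), c(4, 6), "classification", 2,
                  input_h = h, input_w = w)
}

# a network whose output is exactly `values` for any input (head W = 0)
make_const_net <- function(config, values, seed = 1) {
  net <- build_network(config, seed)
  st <- cnet_state(net)
  st$headW[] <- 0
  st$headb[] <- values
  cnet_restore(net, st)
  net
}

cnet_state <- function(net) ettcascade:::cnet_get_state(net$ptr)
cnet_restore <- function(net, st) ettcascade:::cnet_set_state(net$ptr, st)

rand_image <- function(h = 16, w = h) matrix(rnorm(h * w), h, w)
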