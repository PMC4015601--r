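# 10-frame drift, 1 px/frame to the right
n_frames: 10
dx: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9]
dy: 0
rotate: 0
scale: 1
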