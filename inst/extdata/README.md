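# External data

`video_s1.avi` (not included): the worked-example stereomicroscope recording
of a contracting rat mesenteric lymphatic, available as supplementary
material of the original publication describing this workflow. It is not
redistributable here. To run the reproduction test, convert the recording to
uncompressed RGB24 AVI and place it in this directory (or set
`options(lymphpulse.video_s1 = "/path/to/video_s1.avi")`).
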