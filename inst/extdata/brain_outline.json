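{"template":"head_top","outline":[[0.5,0.97],[0.5421,0.9677],[0.5839,0.961],[0.6248,0.9498],[0.6646,0.9342],[0.7027,0.9145],[0.7389,0.8908],[0.7728,0.8633],[0.8041,0.8323],[0.8324,0.7982],[0.8575,0.7611],[0.8792,0.7216],[0.8973,0.6799],[0.9115,0.6364],[0.9217,0.5917],[0.9279,0.5461],[0.93,0.5],[0.9279,0.4542],[0.9217,0.4094],[0.9115,0.3659],[0.8973,0.3243],[0.8792,0.2847],[0.8575,0.2476],[0.8324,0.2132],[0.8041,0.1818],[0.7728,0.1535],[0.7389,0.1287],[0.7027,0.1074],[0.6646,0.0898],[0.6248,0.0761],[0.5839,0.0662],[0.5421,0.0602],[0.5,0.0582],[0.4579,0.0602],[0.4161,0.0662],[0.3752,0.0761],[0.3354,0.0898],[0.2973,0.1074],[0.2611,0.1287],[0.2272,0.1535],[0.1959,0.1818],[0.1676,0.2132],[0.1425,0.2476],[0.1208,0.2847],[0.1027,0.3243],[0.0885,0.3659],[0.0783,0.4094],[0.0721,0.4542],[0.07,0.5],[0.0721,0.5461],[0.0783,0.5917],[0.0885,0.6364],[0.1027,0.6799],[0.1208,0.7216],[0.1425,0.7611],[0.1676,0.7982],[0.1959,0.8323],[0.2272,0.8633],[0.2611,0.8908],[0.2973,0.9145],[0.3354,0.9342],[0.3752,0.9498],[0.4161,0.961],[0.4579,0.9677]]}
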