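name,r,g,b,hex,layer
White,255,255,255,#FFFFFF,core
Pink,255,192,203,#FFC0CB,core
Red,255,0,0,#FF0000,core
Orange,255,165,0,#FFA500,core
Yellow,255,255,0,#FFFF00,core
Bright Yellow,255,234,0,#FFEA00,core
Green,0,128,0,#008000,core
Blue,0,0,255,#0000FF,core
Blue White,173,216,230,#ADD8E6,core
Blue Gray,102,153,204,#6699CC,core
Indigo,75,0,130,#4B0082,core
Violet,143,0,255,#8F00FF,core
Brown,150,75,0,#964B00,core
Light Brown,196,164,132,#C4A484,core
Gray Brown,126,109,90,#7E6D5A,core
Black,0,0,0,#000000,core
Bright White,248,248,255,#F8F8FF,core
Non-pigmented,,,,,dermoscopy
Hypopigmented,,,,,dermoscopy
Pigmented,,,,,dermoscopy
Dark,,,,,dermoscopy
Uniform,,,,,dermoscopy
Variable,,,,,dermoscopy
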