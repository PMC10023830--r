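# kind=ddi directed=false version=ring5
from	to
SD00001	SD00002
SD00002	SD00003
SD00003	SD00004
SD00004	SD00005
SD00005	SD00001
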