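<svg xmlns="http://www.w3.org/2000/svg" width="500" height="500" viewBox="0 0 500 500">
<rect width="500" height="500" fill="white"/>
<path d="M250.000,10.000 A240.000,240.000 0 0,1 457.846,130.000 L430.133,146.000 A208.000,208.000 0 0,0 250.000,42.000 Z" fill="#C6DBEF" stroke="black" stroke-width="1"/>
<path d="M457.846,130.000 A240.000,240.000 0 0,1 250.000,490.000 L250.000,458.000 A208.000,208.000 0 0,0 430.133,146.000 Z" fill="#4292C6" stroke="black" stroke-width="1"/>
<path d="M250.000,490.000 A240.000,240.000 0 0,1 250.000,10.000 L250.000,42.000 A208.000,208.000 0 0,0 250.000,458.000 Z" fill="#C6DBEF" stroke="black" stroke-width="1"/>
<path d="M250.000,46.000 A204.000,204.000 0 0,1 426.669,148.000 L398.956,164.000 A172.000,172.000 0 0,0 250.000,78.000 Z" fill="#FEE08B" stroke="black" stroke-width="1"/>
<path d="M426.669,148.000 A204.000,204.000 0 0,1 250.000,454.000 L250.000,422.000 A172.000,172.000 0 0,0 398.956,164.000 Z" fill="#4292C6" stroke="black" stroke-width="1"/>
<path d="M250.000,454.000 A204.000,204.000 0 0,1 250.000,46.000 L250.000,78.000 A172.000,172.000 0 0,0 250.000,422.000 Z" fill="#FEE08B" stroke="black" stroke-width="1"/>
<path d="M250.000,82.000 A168.000,168.000 0 0,1 395.492,166.000 L367.779,182.000 A136.000,136.000 0 0,0 250.000,114.000 Z" fill="#FEE08B" stroke="black" stroke-width="1"/>
<path d="M395.492,166.000 A168.000,168.000 0 0,1 250.000,418.000 L250.000,386.000 A136.000,136.000 0 0,0 367.779,182.000 Z" fill="#4292C6" stroke="black" stroke-width="1"/>
<path d="M250.000,418.000 A168.000,168.000 0 0,1 250.000,82.000 L250.000,114.000 A136.000,136.000 0 0,0 250.000,386.000 Z" fill="#FEE08B" stroke="black" stroke-width="1"/>
<path d="M250.000,118.000 A132.000,132.000 0 0,1 364.315,184.000 L336.603,200.000 A100.000,100.000 0 0,0 250.000,150.000 Z" fill="#F46D43" stroke="black" stroke-width="1"/>
<path d="M364.315,184.000 A132.000,132.000 0 0,1 250.000,382.000 L250.000,350.000 A100.000,100.000 0 0,0 336.603,200.000 Z" fill="#4292C6" stroke="black" stroke-width="1"/>
<path d="M250.000,382.000 A132.000,132.000 0 0,1 250.000,118.000 L250.000,150.000 A100.000,100.000 0 0,0 250.000,350.000 Z" fill="#F46D43" stroke="black" stroke-width="1"/>
<path d="M250.000,154.000 A96.000,96.000 0 0,1 333.138,202.000 L305.426,218.000 A64.000,64.000 0 0,0 250.000,186.000 Z" fill="#006837" stroke="black" stroke-width="1"/>
<path d="M333.138,202.000 A96.000,96.000 0 0,1 250.000,346.000 L250.000,314.000 A64.000,64.000 0 0,0 305.426,218.000 Z" fill="#4292C6" stroke="black" stroke-width="1"/>
<path d="M250.000,346.000 A96.000,96.000 0 0,1 250.000,154.000 L250.000,186.000 A64.000,64.000 0 0,0 250.000,314.000 Z" fill="#006837" stroke="black" stroke-width="1"/>
</svg>
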